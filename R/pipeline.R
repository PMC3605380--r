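## pipeline: orchestrate trim -> dual-k assembly -> chloroplast binning ->
## two-half scaffolding -> read mapping -> pooled SNP calling, with files,
## logging and provenance; plus the subsampling and SNP-recovery
## experiments used to characterise the method.

#' Pipeline configuration
#'
#' Collects the stage parameters of the whole-plastome protocol. Input
#' reads/references may be file paths (FASTQ/FASTA) or in-memory objects
#' (`read_pairs`, `quadripartite_genome`, named sequence vectors).
#'
#' @param reads paired reads: a `read_pairs` object or `c(r1, r2)` FASTQ
#'   paths.
#' @param reference distant scaffold reference: `quadripartite_genome`,
#'   DNA string, or FASTA path.
#' @param database plastome database: named sequence vector, `DNAStringSet`,
#'   or multi-FASTA path.
#' @param out_dir output directory (`NULL` for no files).
#' @param k_values two (or more) odd k-mer sizes for the dual assembly.
#' @param min_contig_len minimum contig length.
#' @param trim a [trim_config()].
#' @param evalue_max chloroplast-bin threshold ("E-value of zero").
#' @param ssc_overhang,overlap [split_reference()] parameters.
#' @param min_ir_len minimum IR length for annotation.
#' @param mapping a [mapping_config()].
#' @param mvf,min_cov SNP-calling thresholds.
#' @param seed master seed recorded in outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(reads, reference, database, out_dir = NULL,
                       k_values = c(31L, 41L), min_contig_len = 200L,
                       trim = trim_config(), evalue_max = 1e-180,
                       ssc_overhang = 1000L, overlap = 3000L,
                       min_ir_len = 1000L, mapping = mapping_config(),
                       mvf = 0.2, min_cov = 10L, seed = 1L) {
  if (is.null(reference))
    stop("config field `reference` is required when scaffolding is enabled",
         call. = FALSE)
  if (is.character(reads)) {
    missing <- reads[!file.exists(reads)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  structure(list(reads = reads, reference = reference, database = database,
                 out_dir = out_dir, k_values = as.integer(k_values),
                 min_contig_len = as.integer(min_contig_len), trim = trim,
                 evalue_max = evalue_max,
                 ssc_overhang = as.integer(ssc_overhang),
                 overlap = as.integer(overlap),
                 min_ir_len = as.integer(min_ir_len), mapping = mapping,
                 mvf = mvf, min_cov = as.integer(min_cov),
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_reads <- function(x) {
  if (inherits(x, "read_pairs")) return(x)
  if (is.character(x) && length(x) == 2L) return(read_fastq_pairs(x[1], x[2]))
  stop("reads must be a read_pairs object or two FASTQ paths", call. = FALSE)
}

resolve_reference <- function(x) {
  if (inherits(x, "quadripartite_genome")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    return(as.character(seqs[[1]]))
  }
  if (is.character(x) && length(x) == 1L) return(x)
  stop("unsupported reference input", call. = FALSE)
}

#' Run the whole chloroplast-genome pipeline
#'
#' Executes trim, de novo assembly at each configured k, E-value binning
#' against the plastome database, two-half scaffolding with IR duplication,
#' read mapping back to the consensus, and pooled SNP calling. Each stage's
#' output is persisted to `out_dir` (when set) in standard formats, and a
#' run report collecting assembly statistics, region lengths, junctions and
#' the SNP table is returned.
#'
#' @param config a [run_config()].
#' @param log function used for progress messages (default [message()];
#'   pass `function(...) {}` to silence).
#' @return a `run_report` list.
#' @export
run_all <- function(config, log = message) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    log(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  od <- config$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)
  save_to <- function(f) if (is.null(od)) NULL else file.path(od, f)

  reads <- stage("load reads", resolve_reads(config$reads))
  pre_stats <- read_stats(reads)
  reads <- stage("quality trim", trim_pairs(reads, config$trim))
  post_stats <- read_stats(reads)

  asms <- stage("de novo assembly (dual k)", lapply(config$k_values, function(k)
    assemble(reads, k, min_contig_len = config$min_contig_len)))
  contigs <- rbindlist(asms)
  class(contigs) <- c("contig_set", class(contigs))
  asm_stats <- do.call(rbind, lapply(asms, assembly_stats))
  asm_stats <- cbind(data.frame(k = config$k_values), asm_stats)
  if (!is.null(od)) {
    write_contigs(contigs, save_to("contigs.fasta"))
    write.table(asm_stats, save_to("assembly_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  bin <- stage("chloroplast binning", bin_contigs(
    contigs, config$database, evalue_max = config$evalue_max))
  if (!is.null(od)) write_hits(bin$hits, save_to("bin_hits.tsv"))
  if (!nrow(bin$kept))
    stop("stage 'chloroplast binning' retained no contigs", call. = FALSE)

  reference <- resolve_reference(config$reference)
  scaffolds <- stage("split reference", split_reference(
    reference, ssc_overhang = config$ssc_overhang, overlap = config$overlap,
    min_ir_len = config$min_ir_len))
  placements <- stage("contig placement", place_contigs(bin$kept, scaffolds))
  consensus <- stage("consensus and merge", consensus_and_merge(
    placements, bin$kept, scaffolds, min_ir_len = config$min_ir_len))
  if (!is.null(od)) {
    hdr <- sprintf("consensus length=%d seed=%d", nchar(consensus$sequence),
                   config$seed)
    x <- Biostrings::DNAStringSet(consensus$sequence)
    names(x) <- paste("consensus", hdr)
    Biostrings::writeXStringSet(x, save_to("consensus.fasta"))
    write_region_annotation(consensus, save_to("regions.gff3"),
                            save_to("junctions.bed"))
    write.table(placements, save_to("placements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  alignments <- stage("read mapping", map_reads(reads, consensus$sequence,
                                                config$mapping))
  pile <- stage("pileup", pileup(alignments, consensus$sequence))
  cov <- coverage(alignments, consensus$sequence)
  calls <- stage("SNP calling", call_snps(pile, mvf = config$mvf,
                                          min_cov = config$min_cov))
  if (!is.null(od)) {
    write_sam(alignments, "consensus", nchar(consensus$sequence),
              save_to("alignments.sam"))
    write_pileup(pile, save_to("pileup.tsv"))
    write_vcf(list(POOL1 = calls), "consensus", nchar(consensus$sequence),
              save_to("calls.vcf"),
              provenance = sprintf("source=plastidkit seed=%d", config$seed))
  }

  report <- structure(list(
    seed = config$seed,
    reads_before = pre_stats, reads_after = post_stats,
    assembly_stats = asm_stats,
    n_contigs = nrow(contigs), n_chloroplast_contigs = nrow(bin$kept),
    placements = placements,
    consensus = consensus,
    consensus_length = nchar(consensus$sequence),
    region_lengths = if (nrow(consensus$regions))
      setNames(consensus$regions$end - consensus$regions$start + 1L,
               consensus$regions$region) else NULL,
    junctions = consensus$junctions,
    coverage = cov,
    n_snps = nrow(calls), snps = calls),
    class = "run_report")
  if (!is.null(od)) {
    saveRDS_free <- file.path(od, "report.yaml")
    yaml::write_yaml(report_to_list(report), saveRDS_free)
  }
  report
}

report_to_list <- function(r) {
  list(seed = r$seed,
       reads_before = as.list(r$reads_before),
       reads_after = as.list(r$reads_after),
       assembly_stats = lapply(seq_len(nrow(r$assembly_stats)), function(i)
         as.list(r$assembly_stats[i, ])),
       n_contigs = r$n_contigs,
       n_chloroplast_contigs = r$n_chloroplast_contigs,
       consensus_length = r$consensus_length,
       region_lengths = as.list(r$region_lengths),
       coverage = r$coverage,
       n_snps = r$n_snps)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> consensus %s bp, coverage %.1fx, %d SNP call(s)\n",
              format(x$consensus_length, big.mark = ","), x$coverage,
              x$n_snps))
  if (!is.null(x$region_lengths))
    cat("  regions:", paste(names(x$region_lengths),
                            format(x$region_lengths, big.mark = ","),
                            collapse = " | "), "\n")
  invisible(x)
}

#' Subsampling experiment: coverage needed for full-genome recovery
#'
#' Reruns the assembly arm of the pipeline on every-nth subsamples of the
#' reads and reports, per fraction, the mean mapped coverage, whether the
#' full genome was recovered (consensus circularly identical to the
#' full-data consensus, all four junctions present), and the SNP recovery
#' when truth sites are supplied.
#'
#' @param config a [run_config()].
#' @param fractions subset of `1 / 2^k` fractions (e.g. `c(0.5, 0.25)`).
#' @param truth_sites optional integer positions of planted variants.
#' @param log progress function.
#' @return data.frame with `fraction`, `coverage`, `recovered`, `n_snps`,
#'   `snps_recovered`.
#' @export
subsample_experiment <- function(config, fractions = c(0.5, 0.25, 0.125),
                                 truth_sites = NULL, log = message) {
  stopifnot(inherits(config, "run_config"))
  steps <- 1 / fractions
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("fractions must be of the form 1/n", call. = FALSE)
  full <- run_all(config, log = log)
  reads <- resolve_reads(config$reads)
  rows <- lapply(seq_along(fractions), function(i) {
    sub <- subsample_every_nth(reads, round(steps[i]))
    cfg <- config
    cfg$reads <- sub
    rep_i <- tryCatch(run_all(cfg, log = log), error = function(e) NULL)
    if (is.null(rep_i)) {
      return(data.frame(fraction = fractions[i], coverage = NA_real_,
                        recovered = FALSE, n_snps = NA_integer_,
                        snps_recovered = NA_integer_))
    }
    recovered <- sequences_equal_circular(rep_i$consensus$sequence,
                                          full$consensus$sequence) &&
      nrow(rep_i$junctions) == 4L
    data.frame(fraction = fractions[i], coverage = rep_i$coverage,
               recovered = recovered, n_snps = rep_i$n_snps,
               snps_recovered = if (is.null(truth_sites)) NA_integer_
               else sum(unique(rep_i$snps$pos) %in% truth_sites))
  })
  out <- rbind(
    data.frame(fraction = 1, coverage = full$coverage, recovered = TRUE,
               n_snps = full$n_snps,
               snps_recovered = if (is.null(truth_sites)) NA_integer_
               else sum(unique(full$snps$pos) %in% truth_sites)),
    do.call(rbind, rows))
  out
}

#' Two-pool pooled-sequencing SNP recovery experiment
#'
#' Simulates two pools of `n_individuals` haplotypes of one genome carrying
#' `n_sites` planted SNPs (each carried by one individual per pool, i.e. a
#' within-pool frequency of 1/n), sequences each pool to `coverage_x`, maps
#' the reads back to the generating genome and calls SNPs per pool at the
#' given thresholds. Recovery is assessed on the union of the two pools'
#' calls, mirroring SNP discovery across two mapped datasets.
#'
#' @param genome a `quadripartite_genome` (default: a 10.5 kb miniature).
#' @param n_sites planted variant sites.
#' @param n_individuals pool size.
#' @param coverage_x per-pool mean coverage.
#' @param per_base_error sequencing error rate.
#' @param mvf,min_cov calling thresholds.
#' @param mapping a [mapping_config()] (seed is re-derived per pool).
#' @param seed master seed.
#' @return list with `planted` (positions), `calls` (per pool),
#'   `recovered` (union positions also planted), `false_positives`
#'   (called but not planted), `comparison` ([compare_pools()] output),
#'   `coverage` (per pool).
#' @export
snp_recovery_experiment <- function(genome = NULL, n_sites = 10L,
                                    n_individuals = 4L, coverage_x = 200,
                                    per_base_error = 0.002, mvf = 0.2,
                                    min_cov = 10L,
                                    mapping = mapping_config(), seed = 1L) {
  if (is.null(genome))
    genome <- make_genome(6000, 1500, 1500, seed = seed + 101L)
  truth <- genome_sequence(genome)
  L <- nchar(truth)
  reg <- genome_regions(genome)
  with_seed(seed, {
    ## plant sites in the single-copy regions, clear of the junctions
    sc <- c(seq(reg$start[1] + 100L, reg$end[1] - 100L),
            seq(reg$start[3] + 100L, reg$end[3] - 100L))
    pos <- sort(sample(sc, n_sites))
    sites <- lapply(pos, function(p) {
      ref <- substr(truth, p, p)
      list(pos = p, alt = sample(setdiff(DNA_BASES, ref), 1L), carriers = NA)
    })
    carr <- lapply(seq_len(n_sites), function(i)
      c(sample.int(n_individuals, 1L), sample.int(n_individuals, 1L)))
    for (i in seq_len(n_sites)) sites[[i]]$carriers <- carr[[i]]
  })
  pool_sites <- function(k)
    lapply(sites, function(s)
      list(pos = s$pos, alt = s$alt, carriers = s$carriers[k]))
  pools <- lapply(1:2, function(k)
    make_pool(genome, n_individuals, pool_sites(k),
              pool_id = sprintf("pool%d", k)))
  npairs <- round(coverage_x * L / 200)
  results <- lapply(1:2, function(k) {
    rp <- simulate_reads(pools[[k]], sim_config(
      n_pairs = npairs, cp_fraction = 1, per_base_error = per_base_error,
      insert_mean = 460L, seed = seed + 200L + k))
    rp <- trim_pairs(rp)
    cfg <- mapping
    cfg$seed <- seed + 300L + k
    al <- map_reads(rp, truth, cfg)
    pi <- pileup(al, truth)
    list(calls = call_snps(pi, mvf = mvf, min_cov = min_cov,
                           pool_id = sprintf("pool%d", k)),
         pile = pi, cov = coverage(al, L))
  })
  calls <- lapply(results, `[[`, "calls")
  names(calls) <- c("pool1", "pool2")
  piles <- lapply(results, `[[`, "pile")
  names(piles) <- names(calls)
  called <- sort(unique(unlist(lapply(calls, `[[`, "pos"))))
  list(planted = pos,
       calls = calls,
       recovered = intersect(called, pos),
       false_positives = setdiff(called, pos),
       comparison = compare_pools(calls, piles),
       coverage = vapply(results, `[[`, 0, "cov"))
}
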