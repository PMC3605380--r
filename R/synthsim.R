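## synthsim: synthetic quadripartite plastomes, pooled haplotypes and
## paired-end shotgun reads. Every downstream stage is testable against the
## truth tables produced here.

#' Construct a quadripartite plastome object
#'
#' A circular plastid genome in the canonical LSC-IRb-SSC-IRa layout,
#' linearised at LSC base 1. Only the three distinct region sequences are
#' stored; IRb equals `ir` and IRa is its reverse complement by construction.
#'
#' @param lsc,ssc,ir DNA strings for the large single-copy, small single-copy
#'   and inverted-repeat regions.
#' @param id label for the genome.
#' @return an object of class `quadripartite_genome`.
#' @seealso [make_genome()], [genome_sequence()]
#' @export
quadripartite_genome <- function(lsc, ssc, ir, id = "genome") {
  check_dna(lsc, "lsc"); check_dna(ssc, "ssc"); check_dna(ir, "ir")
  stopifnot(length(lsc) == 1L, length(ssc) == 1L, length(ir) == 1L)
  if (min(nchar(lsc), nchar(ssc), nchar(ir)) < 1L)
    stop("all region lengths must be positive", call. = FALSE)
  structure(list(lsc = lsc, ssc = ssc, ir = ir, id = as.character(id)),
            class = "quadripartite_genome")
}

#' @export
print.quadripartite_genome <- function(x, ...) {
  cat(sprintf(
    "<quadripartite_genome '%s'> LSC %s bp | IRb %s bp | SSC %s bp | IRa %s bp (total %s bp)\n",
    x$id, format(nchar(x$lsc), big.mark = ","),
    format(nchar(x$ir), big.mark = ","), format(nchar(x$ssc), big.mark = ","),
    format(nchar(x$ir), big.mark = ","),
    format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' Full linear sequence of a quadripartite genome
#'
#' Returns LSC + IRb + SSC + IRa with IRa the reverse complement of IRb,
#' linearised at LSC base 1.
#'
#' @param genome a `quadripartite_genome`.
#' @return a single DNA string.
#' @export
genome_sequence <- function(genome) {
  stopifnot(inherits(genome, "quadripartite_genome"))
  paste0(genome$lsc, genome$ir, genome$ssc, revcomp(genome$ir))
}

#' @rdname genome_sequence
#' @export
genome_length <- function(genome) {
  nchar(genome$lsc) + nchar(genome$ssc) + 2L * nchar(genome$ir)
}

#' Region coordinates of a quadripartite genome
#'
#' @param genome a `quadripartite_genome`.
#' @return data.frame with columns `region`, `start`, `end` (1-based
#'   inclusive) in LSC, IRb, SSC, IRa order.
#' @export
genome_regions <- function(genome) {
  l <- nchar(genome$lsc); i <- nchar(genome$ir); s <- nchar(genome$ssc)
  data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, l + 1L, l + i + 1L, l + i + s + 1L),
    end = c(l, l + i, l + i + s, l + 2L * i + s),
    stringsAsFactors = FALSE)
}

#' Generate a random quadripartite plastome
#'
#' Region sequences are i.i.d. uniform DNA, so single-copy regions are
#' repeat-free with overwhelming probability while the IR is, by construction,
#' present in two reverse-complementary copies.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp (all > 0).
#' @param seed integer seed; the genome is deterministic per seed.
#' @param id genome label.
#' @return a `quadripartite_genome`.
#' @export
#' @examples
#' g <- make_genome(1000, 200, 300, seed = 1)
#' genome_length(g)  # 1800
make_genome <- function(lsc_len, ssc_len, ir_len, seed, id = "synthetic_plastome") {
  for (nm in c("lsc_len", "ssc_len", "ir_len"))
    stop_if_not_scalar_number(get(nm), nm)
  if (min(lsc_len, ssc_len, ir_len) <= 0)
    stop("region lengths must be positive", call. = FALSE)
  with_seed(seed, {
    quadripartite_genome(random_dna(lsc_len), random_dna(ssc_len),
                         random_dna(ir_len), id = id)
  })
}

#' Derive a diverged relative of a genome
#'
#' Emulates a distant scaffold reference (e.g. a confamilial or
#' different-family plastome) by applying random substitutions and short
#' (1-10 bp) indels independently to the LSC, SSC and IR region sequences and
#' regenerating IRa, so the quadripartite invariants are preserved.
#'
#' @param genome a `quadripartite_genome`.
#' @param sub_rate per-site substitution probability, in `[0, 0.5)`.
#' @param indel_rate per-site probability of starting an indel, in `[0, 0.5)`.
#' @param seed integer seed.
#' @param id label for the diverged genome.
#' @return a new `quadripartite_genome`.
#' @export
diverge <- function(genome, sub_rate, indel_rate, seed,
                    id = paste0(genome$id, "_diverged")) {
  stopifnot(inherits(genome, "quadripartite_genome"))
  for (r in c(sub_rate, indel_rate))
    if (!is.numeric(r) || r < 0 || r >= 0.5)
      stop("rates must lie in [0, 0.5)", call. = FALSE)
  with_seed(seed, {
    quadripartite_genome(
      mutate_region(genome$lsc, sub_rate, indel_rate),
      mutate_region(genome$ssc, sub_rate, indel_rate),
      mutate_region(genome$ir, sub_rate, indel_rate),
      id = id)
  })
}

mutate_region <- function(s, sub_rate, indel_rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit))
      ch[hit] <- vapply(ch[hit],
                        function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  if (indel_rate > 0) {
    sites <- which(runif(n) < indel_rate)
    # apply right-to-left so earlier coordinates stay valid
    for (p in rev(sites)) {
      len <- sample.int(10L, 1L)
      if (runif(1) < 0.5) {                    # deletion
        drop <- p:min(n, p + len - 1L)
        ch <- ch[-drop]
        n <- length(ch)
      } else {                                 # insertion after p
        ins <- sample(DNA_BASES, len, replace = TRUE)
        ch <- append(ch, ins, after = p)
        n <- length(ch)
      }
    }
  }
  if (length(ch) < 1L) ch <- sample(DNA_BASES, 1L)
  paste(ch, collapse = "")
}

#' Build a pool of haplotypes with planted variants
#'
#' Models equimolar pooling of several individuals into one sequencing
#' library: each haplotype is the base genome plus the planted substitutions
#' it carries. With `n_individuals = 4` a site carried by one individual has
#' an expected pooled allele frequency of 25%.
#'
#' @param genome a `quadripartite_genome`.
#' @param n_individuals number of pooled haplotypes.
#' @param variant_sites list of `list(pos =, alt =, carriers =)` entries:
#'   1-based position on the full linear sequence, alternative base, and the
#'   integer indices (subset of `1:n_individuals`) of carriers.
#' @param seed integer seed (reserved for randomised site generation by
#'   callers; haplotype construction itself is deterministic).
#' @param pool_id label prefix for haplotype ids.
#' @return list of `haplotype` objects (fields `base_genome`, `edits`, `id`).
#' @export
make_pool <- function(genome, n_individuals, variant_sites = list(), seed = 1L,
                      pool_id = "pool") {
  stopifnot(inherits(genome, "quadripartite_genome"), n_individuals >= 1L)
  full <- genome_sequence(genome)
  L <- nchar(full)
  seen <- integer(0)
  for (v in variant_sites) {
    stopifnot(all(c("pos", "alt", "carriers") %in% names(v)))
    if (v$pos < 1L || v$pos > L)
      stop("variant position outside genome", call. = FALSE)
    if (v$pos %in% seen)
      stop("duplicate variant position", call. = FALSE)
    seen <- c(seen, v$pos)
    if (length(v$carriers) &&
        (min(v$carriers) < 1L || max(v$carriers) > n_individuals))
      stop("carrier index out of range", call. = FALSE)
    ref <- substr(full, v$pos, v$pos)
    if (!v$alt %in% DNA_BASES || identical(v$alt, ref))
      stop("alt base must be a DNA base different from the reference",
           call. = FALSE)
  }
  lapply(seq_len(n_individuals), function(i) {
    ed <- Filter(function(v) i %in% v$carriers, variant_sites)
    edits <- if (length(ed)) {
      data.frame(pos = vapply(ed, `[[`, 0, "pos"),
                 ref = vapply(ed, function(v) substr(full, v$pos, v$pos), ""),
                 alt = vapply(ed, `[[`, "", "alt"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pos = integer(0), ref = character(0), alt = character(0))
    }
    structure(list(base_genome = genome, edits = edits,
                   id = sprintf("%s_ind%d", pool_id, i)),
              class = "haplotype")
  })
}

#' Full sequence of a haplotype (base genome with its edits applied)
#' @param hap a `haplotype` from [make_pool()].
#' @return a DNA string.
#' @export
haplotype_sequence <- function(hap) {
  stopifnot(inherits(hap, "haplotype"))
  s <- genome_sequence(hap$base_genome)
  if (nrow(hap$edits)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    stopifnot(all(ch[hap$edits$pos] == hap$edits$ref))
    ch[hap$edits$pos] <- hap$edits$alt
    s <- paste(ch, collapse = "")
  }
  s
}

#' Pooled allele fraction of each planted site across a haplotype pool
#' @param pool list of haplotypes from [make_pool()].
#' @return data.frame with `pos`, `ref`, `alt`, `carriers`, `frequency`.
#' @export
pool_allele_fractions <- function(pool) {
  ed <- do.call(rbind, lapply(pool, `[[`, "edits"))
  if (is.null(ed) || !nrow(ed))
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      carriers = integer(0), frequency = numeric(0)))
  agg <- aggregate(list(carriers = ed$pos), by = ed[c("pos", "ref", "alt")],
                   FUN = length)
  agg <- agg[order(agg$pos), , drop = FALSE]
  agg$frequency <- agg$carriers / length(pool)
  rownames(agg) <- NULL
  agg
}

#' Simulation configuration for paired-end shotgun reads
#'
#' Defaults emulate a typical paired-end shotgun run for plastome skimming:
#' 100 bp reads, ~460 bp inserts, and chloroplast molecules as a ~5% minority
#' of total genomic DNA (the remainder simulated as a uniform-random decoy
#' background).
#'
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert size distribution (bp); inserts are
#'   drawn normal and clamped to at least `read_len`.
#' @param per_base_error per-base substitution error probability in `[0, 1)`.
#' @param n_pairs number of read pairs to generate.
#' @param seed integer seed.
#' @param cp_fraction fraction of pairs drawn from the plastome haplotypes
#'   (in `(0, 1]`); the rest come from the decoy background.
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_len = 100L, insert_mean = 460L, insert_sd = 50L,
                       per_base_error = 0.002, n_pairs = 10000L, seed = 1L,
                       cp_fraction = 0.05) {
  if (per_base_error < 0 || per_base_error >= 1)
    stop("per_base_error must lie in [0, 1)", call. = FALSE)
  if (insert_mean < read_len)
    stop("insert_mean must be at least read_len", call. = FALSE)
  if (cp_fraction <= 0 || cp_fraction > 1)
    stop("cp_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 per_base_error = as.numeric(per_base_error),
                 n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed),
                 cp_fraction = as.numeric(cp_fraction)),
            class = "sim_config")
}

#' Simulate paired-end reads from a pool of haplotypes
#'
#' Fragments are drawn uniformly across haplotypes and circular coordinates
#' (inserts may span the origin); mate 1 is the fragment 5' end, mate 2 the
#' reverse complement of its 3' end. Substitution errors are applied per base
#' at `per_base_error` and the constant quality string encodes that error rate
#' (Phred+33). With `cp_fraction < 1` the remaining pairs are drawn from an
#' i.i.d. uniform decoy background, emulating the nuclear/mitochondrial bulk
#' of a total-DNA shotgun library.
#'
#' @param haplotypes non-empty list of `haplotype` objects ([make_pool()]).
#' @param config a [sim_config()].
#' @return a `read_pairs` object: list with `id`, `r1`, `r2`, `q1`, `q2`
#'   (character vectors) and a `truth` data.table (`read_id`, `source`,
#'   `hap`, `start`, `insert`).
#' @export
simulate_reads <- function(haplotypes, config = sim_config()) {
  if (!length(haplotypes)) stop("haplotypes must be non-empty", call. = FALSE)
  stopifnot(inherits(config, "sim_config"))
  if (config$n_pairs <= 0) stop("n_pairs must be positive", call. = FALSE)
  seqs <- vapply(haplotypes, haplotype_sequence, "")
  L <- nchar(seqs[[1]])
  stopifnot(all(nchar(seqs) == L))
  rl <- config$read_len

  with_seed(config$seed, {
    n_cp <- round(config$n_pairs * config$cp_fraction)
    n_decoy <- config$n_pairs - n_cp
    hap_idx <- if (n_cp) sample.int(length(seqs), n_cp, replace = TRUE)
               else integer(0)
    inserts <- pmax(rl, as.integer(round(
      rnorm(config$n_pairs, config$insert_mean, config$insert_sd))))
    starts <- if (n_cp) sample.int(L, n_cp, replace = TRUE) else integer(0)

    frags <- character(config$n_pairs)
    if (n_cp)
      frags[seq_len(n_cp)] <- vapply(seq_len(n_cp), function(i) {
        circular_substr(seqs[[hap_idx[i]]], starts[i], inserts[i])
      }, "")
    if (n_decoy)
      frags[n_cp + seq_len(n_decoy)] <- vapply(
        n_cp + seq_len(n_decoy), function(i) random_dna(inserts[i]), "")

    r1 <- substr(frags, 1L, rl)
    r2 <- revcomp(substr(frags, nchar(frags) - rl + 1L, nchar(frags)))
    if (config$per_base_error > 0) {
      r1 <- apply_seq_errors(r1, config$per_base_error)
      r2 <- apply_seq_errors(r2, config$per_base_error)
    }
    q <- strrep(error_prob_to_qchar(config$per_base_error), rl)
    ids <- sprintf("sim%06d", seq_len(config$n_pairs))
    truth <- data.table(
      read_id = ids,
      source = rep(c("chloroplast", "decoy"), c(n_cp, n_decoy)),
      hap = c(vapply(haplotypes, `[[`, "", "id")[hap_idx],
              rep(NA_character_, n_decoy)),
      start = c(starts, rep(NA_integer_, n_decoy)),
      insert = inserts)
    structure(list(id = ids, r1 = r1, r2 = r2,
                   q1 = rep(q, config$n_pairs), q2 = rep(q, config$n_pairs),
                   truth = truth, config = config),
              class = "read_pairs")
  })
}

apply_seq_errors <- function(reads, p) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < p)
    if (!length(hit)) return(r)
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

error_prob_to_qchar <- function(p) {
  q <- if (p <= 0) 40L else max(2L, min(40L, as.integer(floor(-10 * log10(p)))))
  intToUtf8(q + 33L)
}

#' @export
print.read_pairs <- function(x, ...) {
  src <- if (!is.null(x$truth))
    sprintf(" (%.0f%% chloroplast)", 100 * mean(x$truth$source == "chloroplast"))
  else ""
  cat(sprintf("<read_pairs> %d pairs, read length %d bp%s\n",
              length(x$id), if (length(x$r1)) nchar(x$r1[1]) else 0L, src))
  invisible(x)
}

#' Number of read pairs
#' @param rp a `read_pairs` object.
#' @return integer count of pairs.
#' @export
n_pairs <- function(rp) length(rp$id)

## ---- FASTQ I/O --------------------------------------------------------------

#' Write paired reads to two FASTQ files
#' @param rp a `read_pairs` object.
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(rp, prefix) {
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  write_fastq(rp$r1, rp$q1, paste0(rp$id, "/1"), f1)
  write_fastq(rp$r2, rp$q2, paste0(rp$id, "/2"), f2)
  invisible(c(f1, f2))
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
}

#' Read paired FASTQ files into a `read_pairs` object
#' @param f1,f2 mate FASTQ paths.
#' @return a `read_pairs` object (without simulation truth).
#' @export
read_fastq_pairs <- function(f1, f2) {
  a <- Biostrings::readQualityScaledDNAStringSet(f1)
  b <- Biostrings::readQualityScaledDNAStringSet(f2)
  if (length(a) != length(b))
    stop("mate files have different record counts", call. = FALSE)
  structure(list(id = sub("/[12]$", "", names(a)),
                 r1 = as.character(a), r2 = as.character(b),
                 q1 = as.character(Biostrings::quality(a)),
                 q2 = as.character(Biostrings::quality(b)),
                 truth = NULL, config = NULL),
            class = "read_pairs")
}

#' Write a planted-variant truth table as TSV
#' @param pool list of haplotypes from [make_pool()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_truth_table <- function(pool, path) {
  write.table(pool_allele_fractions(pool), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
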