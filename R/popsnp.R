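## popsnp: map reads onto the consensus, build pileups, and call SNPs in
## pooled samples with minimum-variant-frequency (mvf) and minimum-coverage
## thresholds; compare pools for shared/private variants and fixed
## differences.

#' Read-mapping configuration
#'
#' Defaults follow the optimised pooled-SNP mapping stringency
#' (similarity 0.9, length fraction 0.8); [mapping_preset()] also provides
#' the initial, looser combination.
#'
#' @param similarity minimum fraction of matching bases over the aligned
#'   length.
#' @param length_fraction minimum aligned length as a fraction of read
#'   length.
#' @param match_mode `"random"` places a read with equally good hits at one
#'   of them uniformly at random (seeded); `"unique"` discards such reads.
#' @param seed integer seed for the random placement of multi-mapping reads.
#' @return a `mapping_config` list.
#' @export
mapping_config <- function(similarity = 0.9, length_fraction = 0.8,
                           match_mode = c("random", "unique"), seed = 1L) {
  if (similarity <= 0 || similarity > 1 || length_fraction <= 0 ||
      length_fraction > 1)
    stop("similarity and length_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(similarity = similarity, length_fraction = length_fraction,
                 match_mode = match.arg(match_mode), seed = as.integer(seed)),
            class = "mapping_config")
}

#' @rdname mapping_config
#' @param name `"optimised"` (similarity 0.9, length fraction 0.8) or
#'   `"initial"` (similarity 0.8, length fraction 0.9).
#' @param ... passed on to [mapping_config()].
#' @export
mapping_preset <- function(name = c("optimised", "initial"), ...) {
  switch(match.arg(name),
         optimised = mapping_config(similarity = 0.9, length_fraction = 0.8, ...),
         initial = mapping_config(similarity = 0.8, length_fraction = 0.9, ...))
}

#' Acceptance rule for a candidate read alignment
#'
#' A placement is accepted iff `aligned_len / read_len >= length_fraction`
#' and `matches / aligned_len >= similarity`.
#'
#' @param aligned_len aligned bases of the read.
#' @param read_len full read length.
#' @param matches matching bases within the aligned region.
#' @param config a [mapping_config()].
#' @return logical.
#' @export
alignment_accepted <- function(aligned_len, read_len, matches, config) {
  aligned_len / read_len >= config$length_fraction &
    matches / pmax(aligned_len, 1L) >= config$similarity
}

#' Map reads onto a consensus sequence
#'
#' Seeded, ungapped placement: exact seed words propose candidate start
#' positions on both strands (the consensus is treated as circular, so reads
#' spanning the origin still map), each candidate is verified by direct
#' mismatch counting, and the acceptance rule of [alignment_accepted()] is
#' applied. Reads with several equally good placements - IR-ambiguous reads
#' in particular - are resolved according to `match_mode`.
#'
#' @param reads a `read_pairs` object, or character vector of sequences
#'   (then `quals` may be given).
#' @param consensus consensus DNA string (or `consensus_genome`).
#' @param config a [mapping_config()].
#' @param quals optional quality strings for character input.
#' @param seed_width exact seed word width.
#' @return a `read_alignments` data.table: `read_id`, `pos` (1-based start
#'   on the circular consensus), `strand`, `seq`/`qual` (oriented to the
#'   reference), `aln_len`, `matches`, `n_best` (number of equally good
#'   placements). Attribute `consensus_length` carries the reference length.
#' @export
map_reads <- function(reads, consensus, config = mapping_config(),
                      quals = NULL, seed_width = 13L) {
  if (inherits(consensus, "consensus_genome")) consensus <- consensus$sequence
  if (!nchar(consensus)) stop("consensus must be non-empty", call. = FALSE)
  if (inherits(reads, "read_pairs")) {
    ids <- c(paste0(reads$id, "/1"), paste0(reads$id, "/2"))
    seqs <- c(reads$r1, reads$r2)
    quals <- c(reads$q1, reads$q2)
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("read%06d", seq_along(seqs))
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  }
  L <- nchar(consensus)
  ext <- paste0(consensus, substr(consensus, 1L, max(nchar(seqs))))
  gw <- seq_words(ext, seed_width)
  gw <- gw[pos <= L + seed_width]          # one circular copy of each word
  setkey(gw, word)

  cands <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") seqs else revcomp(seqs)
    n <- nchar(qs)
    offs <- lapply(seq_along(qs), function(i) {
      w <- n[i] - seed_width + 1L
      unique(pmax(1L, c(1L, w %/% 2L, w)))
    })
    qw <- data.table(
      read_idx = rep(seq_along(qs), lengths(offs)),
      off = unlist(offs))
    qw[, word := substr(qs[read_idx], off, off + seed_width - 1L)]
    mm <- gw[qw, on = "word", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(mm)) next
    mm[, start0 := pos - off + 1L]
    mm[, start0 := ((start0 - 1L) %% L) + 1L]
    cand <- unique(mm[, .(read_idx, start0)])
    cand[, strand := strand]
    cands[[length(cands) + 1L]] <- cand
  }
  cand <- rbindlist(cands)
  if (!nrow(cand))
    return(empty_alignments(L))
  ## verify candidates by direct comparison against the circular reference
  cand[, rl := nchar(seqs)[read_idx]]
  qseq <- ifelse(cand$strand == "+", seqs[cand$read_idx],
                 revcomp(seqs[cand$read_idx]))
  refseq <- substring(ext, cand$start0, cand$start0 + cand$rl - 1L)
  cand[, matches := rl - str_mismatches(qseq, refseq)]
  cand[, aln_len := rl]
  cand <- cand[alignment_accepted(aln_len, rl, matches, config)]
  if (!nrow(cand)) return(empty_alignments(L))
  ## best placement(s) per read
  cand[, best := matches == max(matches), by = read_idx]
  cand <- cand[best == TRUE]
  cand[, n_best := .N, by = read_idx]
  with_seed(config$seed, {
    if (config$match_mode == "unique") {
      cand <- cand[n_best == 1L]
    } else {
      cand[, pick := runif(.N)]
      cand <- cand[, .SD[which.max(pick)], by = read_idx]
    }
    out <- cand[, .(
      read_id = ids[read_idx], pos = start0, strand,
      seq = ifelse(strand == "+", seqs[read_idx], revcomp(seqs[read_idx])),
      qual = ifelse(strand == "+", quals[read_idx],
                    vapply(strsplit(quals[read_idx], ""), function(x)
                      paste(rev(x), collapse = ""), "")),
      aln_len, matches, n_best)]
    setorder(out, pos, read_id)
    setattr(out, "consensus_length", L)
    setattr(out, "class", c("read_alignments", class(out)))
    out[]
  })
}

empty_alignments <- function(L) {
  out <- data.table(read_id = character(0), pos = integer(0),
                    strand = character(0), seq = character(0),
                    qual = character(0), aln_len = integer(0),
                    matches = integer(0), n_best = integer(0))
  setattr(out, "consensus_length", L)
  setattr(out, "class", c("read_alignments", class(out)))
  out
}

#' Per-column pileup of mapped reads
#'
#' Counts A/C/G/T (and deletion, always 0 for the ungapped mapper) per
#' consensus column from accepted alignments; bases below `min_base_quality`
#' are excluded from the counts. All consensus positions are reported,
#' including zero-depth columns.
#'
#' @param alignments a `read_alignments` from [map_reads()].
#' @param consensus the consensus DNA string (or `consensus_genome`).
#' @param min_base_quality minimum Phred score for a base to count.
#' @return data.table with `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`, `DEL`.
#' @export
pileup <- function(alignments, consensus, min_base_quality = 13L) {
  if (inherits(consensus, "consensus_genome")) consensus <- consensus$sequence
  L <- nchar(consensus)
  base <- data.table(pos = seq_len(L),
                     ref = strsplit(consensus, "", fixed = TRUE)[[1]])
  if (!nrow(alignments)) {
    out <- base[, .(pos, ref, depth = 0L, A = 0L, C = 0L, G = 0L, T = 0L,
                    DEL = 0L)]
    return(out)
  }
  long <- alignments[, .(
    pos = ((pos + seq_len(aln_len) - 2L) %% L) + 1L,
    base = strsplit(seq, "", fixed = TRUE)[[1L]],
    q = utf8ToInt(qual) - 33L), by = .(read_id)]
  long <- long[q >= min_base_quality & base %chin% DNA_BASES]
  counts <- dcast(long[, .N, by = .(pos, base)], pos ~ base, value.var = "N",
                  fill = 0L)
  for (b in DNA_BASES) if (is.null(counts[[b]])) counts[, (b) := 0L]
  out <- merge(base, counts, by = "pos", all.x = TRUE)
  for (b in DNA_BASES) out[is.na(get(b)), (b) := 0L]
  out[, DEL := 0L]
  out[, depth := A + C + G + T]
  setcolorder(out, c("pos", "ref", "depth", "A", "C", "G", "T", "DEL"))
  out[]
}

#' Mean mapped coverage
#'
#' Total aligned bases divided by consensus length.
#'
#' @param alignments a `read_alignments`.
#' @param consensus consensus string (or `consensus_genome`), or a length.
#' @return mean coverage (x).
#' @export
coverage <- function(alignments, consensus) {
  L <- if (is.numeric(consensus)) consensus else {
    if (inherits(consensus, "consensus_genome")) consensus <- consensus$sequence
    nchar(consensus)
  }
  sum(alignments$aln_len) / L
}

#' Call pooled SNPs from a pileup
#'
#' A site is called when `depth >= min_cov` and some non-reference base
#' reaches `count / depth >= mvf`; one call is emitted per qualifying
#' alternative base. Deletions are never called (SNPs only).
#'
#' @param pile pileup table from [pileup()].
#' @param mvf minimum variant frequency in `(0, 1]`.
#' @param min_cov minimum coverage.
#' @param pool_id label recorded in the calls.
#' @return data.table with `pool_id`, `pos`, `ref`, `alt`, `frequency`,
#'   `depth`.
#' @export
call_snps <- function(pile, mvf = 0.2, min_cov = 10L, pool_id = "pool") {
  if (mvf <= 0 || mvf > 1) stop("mvf must lie in (0, 1]", call. = FALSE)
  if (min_cov < 1) stop("min_cov must be >= 1", call. = FALSE)
  long <- melt(pile[depth >= min_cov],
               id.vars = c("pos", "ref", "depth"),
               measure.vars = DNA_BASES, variable.name = "alt",
               value.name = "count", variable.factor = FALSE)
  calls <- long[alt != ref & count > 0 & count / depth >= mvf]
  out <- calls[, .(pool_id = pool_id, pos, ref, alt,
                   frequency = count / depth, depth)]
  setorder(out, pos, alt)
  out[]
}

#' Compare SNP calls between pools
#'
#' Classifies each called site+allele as shared (called in more than one
#' pool) or private, and scans the pileups for fixed differences: sites
#' where every pool is at least `fixed_cutoff` one allele and the alleles
#' differ between pools.
#'
#' @param calls_by_pool named list of call tables from [call_snps()].
#' @param pileups_by_pool named list of matching [pileup()] tables.
#' @param fixed_cutoff allele-frequency threshold defining "fixed".
#' @return list with `variants` (pos, alt, pools, status) and
#'   `fixed_differences` (pos plus the major allele per pool).
#' @export
compare_pools <- function(calls_by_pool, pileups_by_pool,
                          fixed_cutoff = 0.99) {
  stopifnot(length(calls_by_pool) >= 2L,
            identical(names(calls_by_pool), names(pileups_by_pool)))
  lens <- vapply(pileups_by_pool, nrow, 0L)
  if (length(unique(lens)) != 1L)
    stop("pileups refer to different consensus lengths", call. = FALSE)
  allcalls <- rbindlist(calls_by_pool, idcol = "pool")
  variants <- if (nrow(allcalls)) {
    v <- allcalls[, .(pools = paste(sort(unique(pool)), collapse = ","),
                      n_pools = uniqueN(pool)), by = .(pos, ref, alt)]
    v[, status := ifelse(n_pools > 1L, "shared", "private")]
    setorder(v, pos, alt)
    v
  } else {
    data.table(pos = integer(0), ref = character(0), alt = character(0),
               pools = character(0), n_pools = integer(0),
               status = character(0))
  }
  ## fixed differences from the pileups
  majors <- lapply(names(pileups_by_pool), function(p) {
    pi <- pileups_by_pool[[p]]
    cnt <- as.matrix(pi[, .(A, C, G, T)])
    dep <- pi$depth
    top <- max.col(cnt, ties.method = "first")
    data.table(pos = pi$pos,
               major = DNA_BASES[top],
               fixed = dep > 0L & cnt[cbind(seq_len(nrow(cnt)), top)] >=
                 fixed_cutoff * dep)
  })
  names(majors) <- names(pileups_by_pool)
  wide <- majors[[1]][, .(pos)]
  for (p in names(majors)) {
    wide[, (paste0("major_", p)) := majors[[p]]$major]
    wide[, (paste0("fixed_", p)) := majors[[p]]$fixed]
  }
  fixcols <- paste0("fixed_", names(majors))
  majcols <- paste0("major_", names(majors))
  all_fixed <- Reduce(`&`, lapply(fixcols, function(cn) wide[[cn]]))
  differs <- apply(as.matrix(wide[, ..majcols]), 1L,
                   function(x) length(unique(x)) > 1L)
  fixed_differences <- wide[all_fixed & differs, c("pos", majcols),
                            with = FALSE]
  list(variants = variants, fixed_differences = fixed_differences)
}

## ---- export writers ---------------------------------------------------------

#' Write SNP calls as a VCF v4.2 file
#'
#' Pools appear as sample columns (`GT` omitted; `DP` and `AF` per pool);
#' `AF` in INFO carries the maximum pooled frequency.
#'
#' @param calls_by_pool named list of call tables, or a single call table.
#' @param consensus_id reference sequence name.
#' @param consensus_length reference length for the `##contig` header.
#' @param path output path.
#' @param provenance optional character lines added as `##` headers.
#' @return invisibly, the path.
#' @export
write_vcf <- function(calls_by_pool, consensus_id, consensus_length, path,
                      provenance = NULL) {
  if (is.data.frame(calls_by_pool))
    calls_by_pool <- setNames(list(calls_by_pool),
                              calls_by_pool$pool_id[1] %||% "POOL1")
  pools <- names(calls_by_pool)
  allc <- rbindlist(calls_by_pool)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", consensus_id,
                   as.integer(consensus_length)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Maximum pooled alternate allele frequency\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Pool read depth\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Pooled alternate allele frequency\">",
           if (!is.null(provenance)) paste0("##", provenance),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", pools), collapse = "\t"))
  rows <- character(0)
  if (nrow(allc)) {
    sites <- unique(allc[, .(pos, ref, alt)])
    setorder(sites, pos, alt)
    for (i in seq_len(nrow(sites))) {
      s <- sites[i]
      cells <- vapply(pools, function(p) {
        cp <- calls_by_pool[[p]]
        hit <- cp[cp$pos == s$pos & cp$alt == s$alt, ]
        if (nrow(hit)) sprintf("%d:%.4f", hit$depth[1], hit$frequency[1])
        else ".:."
      }, "")
      af <- max(allc[pos == s$pos & alt == s$alt, frequency])
      rows <- c(rows, paste(c(consensus_id, s$pos, ".", s$ref, s$alt, ".",
                              "PASS", sprintf("AF=%.4f", af), "DP:AF", cells),
                            collapse = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Write read alignments as a SAM file
#'
#' Minimal ungapped SAM export: full-length `M` CIGAR, flag 0/16, `NM` tag.
#'
#' @param alignments a `read_alignments`.
#' @param consensus_id reference name.
#' @param consensus_length reference length.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, consensus_id, consensus_length, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", consensus_id,
                   as.integer(consensus_length)))
  body <- if (nrow(alignments)) {
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
            alignments$read_id,
            ifelse(alignments$strand == "+", 0L, 16L),
            consensus_id, alignments$pos, alignments$aln_len,
            alignments$seq, alignments$qual,
            alignments$aln_len - alignments$matches)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a pileup table as TSV
#' @param pile a [pileup()] table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pileup <- function(pile, path) {
  write.table(pile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
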