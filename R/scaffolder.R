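## scaffolder: order and orient chloroplast contigs against a distant
## reference split into two overlapping halves, vote-majority consensus per
## half, merge across the halves, circularise, and annotate the quadripartite
## structure (LSC/IRb/SSC/IRa) with its four junctions.

#' Split a reference plastome into two overlapping scaffold halves
#'
#' The first half runs from base 1 across IRb and `ssc_overhang` bases into
#' the SSC; the second begins `overlap` bases before the IRb/SSC junction and
#' runs to the reference end (through the SSC and all of IRa). Assembling
#' against the two halves separately is what lets a collapsed IR contig be
#' used in both IR copies.
#'
#' @param reference a `quadripartite_genome`, or a DNA string in which the IR
#'   is detectable ([detect_ir()]).
#' @param ssc_overhang bp of SSC included at the end of the first half.
#' @param overlap bp before the IRb end at which the second half starts
#'   (must satisfy `0 < overlap < |IR|`).
#' @param min_ir_len passed to [detect_ir()] for plain-sequence references.
#' @return a `scaffold_pair`: list with `ref_a`, `ref_b` (each
#'   `list(sequence, start, end)` with 1-based source coordinates),
#'   `overlap_len` (actual interval overlap), and `ir_intervals` (IRb/IRa in
#'   reference coordinates).
#' @export
split_reference <- function(reference, ssc_overhang = 1000L, overlap = 3000L,
                            min_ir_len = 1000L) {
  if (inherits(reference, "quadripartite_genome")) {
    seq <- genome_sequence(reference)
    reg <- genome_regions(reference)
  } else {
    check_dna(reference, "reference")
    seq <- reference
    ann <- detect_ir(seq, min_ir_len = min_ir_len)
    if (!nrow(ann$regions))
      stop("reference has no detectable inverted repeat", call. = FALSE)
    reg <- ann$regions
  }
  L <- nchar(seq)
  irb <- reg[reg$region == "IRb", ]
  ira <- reg[reg$region == "IRa", ]
  ssc <- reg[reg$region == "SSC", ]
  ir_len <- irb$end - irb$start + 1L
  if (overlap <= 0L || overlap >= ir_len)
    stop("overlap must satisfy 0 < overlap < |IR|", call. = FALSE)
  if (ssc_overhang <= 0L || ssc_overhang > ssc$end - ssc$start + 1L)
    stop("ssc_overhang must lie within the SSC", call. = FALSE)
  a_end <- irb$end + as.integer(ssc_overhang)
  b_start <- irb$end - as.integer(overlap) + 1L
  structure(list(
    ref_a = list(sequence = substr(seq, 1L, a_end), start = 1L, end = a_end),
    ref_b = list(sequence = substr(seq, b_start, L), start = b_start, end = L),
    overlap_len = a_end - b_start + 1L,
    ir_intervals = data.frame(
      region = c("IRb", "IRa"),
      start = c(irb$start, ira$start), end = c(irb$end, ira$end))),
    class = "scaffold_pair")
}

#' @export
print.scaffold_pair <- function(x, ...) {
  cat(sprintf("<scaffold_pair> half A: %d..%d (%s bp); half B: %d..%d (%s bp); interval overlap %s bp\n",
              x$ref_a$start, x$ref_a$end,
              format(nchar(x$ref_a$sequence), big.mark = ","),
              x$ref_b$start, x$ref_b$end,
              format(nchar(x$ref_b$sequence), big.mark = ","),
              format(x$overlap_len, big.mark = ",")))
  invisible(x)
}

#' Place binned contigs on the two scaffold halves
#'
#' Each contig is aligned to each half on both strands with
#' [anchor_align()]; a placement is kept when the identity over the aligned
#' core reaches `min_identity`. A contig inside the IR legitimately receives
#' placements on both halves (both IR copies). Contigs whose ends run off a
#' scaffold are flagged as candidate junction-spanning contigs.
#'
#' @param contigs a `contig_set` (normally the chloroplast bin).
#' @param scaffolds a `scaffold_pair` from [split_reference()].
#' @param min_identity minimum identity of the aligned core.
#' @param min_aligned minimum aligned core length in bp (guards against
#'   chance word hits).
#' @param word_len,band passed to [anchor_align()].
#' @return data.table of placements: `contig_id`, `scaffold` (A/B),
#'   `ref_start`, `ref_end` (half-local 1-based), `strand`, `identity`,
#'   `aligned_len`, `in_ir`, `junction_spanning`.
#' @export
place_contigs <- function(contigs, scaffolds, min_identity = 0.7,
                          min_aligned = 50L, word_len = 11L, band = 3000L) {
  stopifnot(inherits(scaffolds, "scaffold_pair"))
  if (!nrow(contigs)) stop("no contigs to place", call. = FALSE)
  halves <- list(A = scaffolds$ref_a, B = scaffolds$ref_b)
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    for (h in names(halves)) {
      ref <- halves[[h]]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") contigs$sequence[i] else
          revcomp(contigs$sequence[i])
        aa <- anchor_align(q, ref$sequence, word_len = word_len, band = band,
                           extend_ends = TRUE)
        if (!aa$found) next
        core <- aa$qend - aa$qstart + 1L
        if (core < min_aligned) next
        idy <- aa$matches / aa$alen
        if (idy < min_identity) next
        ## placement interval in reference-genome coordinates of this half
        glob <- c(aa$rstart, aa$rend) + ref$start - 1L
        in_ir <- any(glob[1] <= scaffolds$ir_intervals$end &
                     glob[2] >= scaffolds$ir_intervals$start)
        rows[[length(rows) + 1L]] <- data.table(
          contig_id = contigs$id[i], scaffold = h,
          ref_start = aa$rstart, ref_end = aa$rend, strand = strand,
          identity = idy, aligned_len = core, in_ir = in_ir,
          junction_spanning = aa$overhang_left > 0L || aa$overhang_right > 0L)
      }
    }
  }
  if (!length(rows))
    stop("no contig could be placed on either scaffold half", call. = FALSE)
  rbindlist(rows)
}

## ---- consensus profile ------------------------------------------------------

PROFILE_ROWS <- c("A", "C", "G", "T", "-")

profile_from_seq <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- matrix(0L, nrow = 5L, ncol = length(ch), dimnames = list(PROFILE_ROWS))
  m[cbind(match(ch, PROFILE_ROWS), seq_along(ch))] <- 1L
  m
}

## majority base per column; ties -> lexicographically smallest base.
## Gap-majority columns are dropped from the emitted string; `map` gives the
## profile column of each emitted character.
profile_consensus <- function(profile) {
  if (is.null(profile) || !ncol(profile))
    return(list(seq = "", map = integer(0), ambiguous = integer(0)))
  top <- apply(profile, 2L, max)
  call_idx <- apply(profile, 2L, which.max)  # first max = lexicographic tie
  base_max <- apply(profile[1:4, , drop = FALSE], 2L, max)
  ambiguous <- which(colSums(profile[1:4, , drop = FALSE] == rep(base_max, each = 4)) > 1L &
                       base_max > 0L)
  is_gap <- profile[5L, ] > base_max
  keep <- which(!is_gap)
  list(seq = paste(PROFILE_ROWS[call_idx[keep]], collapse = ""),
       map = keep,
       ambiguous = intersect(ambiguous, keep))
}

#' Majority vote over the bases observed at one alignment column
#'
#' Ties are broken toward the lexicographically smallest base; the second
#' element of the result reports whether the column was ambiguous.
#'
#' @param bases character vector of observed bases (`A/C/G/T/-`).
#' @return list with `base` and `ambiguous`.
#' @export
#' @examples
#' vote_majority(c("A", "A", "T"))$base  # "A"
vote_majority <- function(bases) {
  tab <- table(factor(bases, levels = PROFILE_ROWS))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  list(base = sort(winners)[1], ambiguous = length(winners) > 1L)
}

## overlay a contig onto the profile using an anchor alignment against the
## emitted consensus string; returns the updated profile or NULL if the
## contig does not align (caller then appends with a zero-length gap)
profile_overlay <- function(profile, seq, min_overlap = 20L,
                            min_overlap_identity = 0.95, word_len = 15L) {
  cons <- profile_consensus(profile)
  aa <- anchor_align(seq, cons$seq, word_len = word_len, extend_ends = FALSE,
                     band = 3000L)
  if (!aa$found || aa$alen < min_overlap ||
      aa$matches / aa$alen < min_overlap_identity)
    return(NULL)
  pch <- strsplit(aa$pattern, "", fixed = TRUE)[[1]]
  sch <- strsplit(aa$subject, "", fixed = TRUE)[[1]]
  rpos <- aa$rstart  # position in emitted consensus
  newcols <- list()  # insertions relative to current profile
  for (j in seq_along(pch)) {
    if (sch[j] == "-") {
      ## insertion in the contig: new column after profile col of rpos-1
      col <- matrix(0L, 5L, 1L, dimnames = list(PROFILE_ROWS))
      col[match(pch[j], PROFILE_ROWS), 1L] <- 1L
      after <- if (rpos > 1L) cons$map[rpos - 1L] else 0L
      newcols[[length(newcols) + 1L]] <- list(after = after, col = col)
    } else {
      pc <- cons$map[rpos]
      profile[match(pch[j], PROFILE_ROWS), pc] <-
        profile[match(pch[j], PROFILE_ROWS), pc] + 1L
      rpos <- rpos + 1L
    }
  }
  ## unaligned contig head/tail: only graft when they extend the profile ends
  if (aa$qstart > 1L && aa$rstart == 1L)
    profile <- cbind(profile_from_seq(substr(seq, 1L, aa$qstart - 1L)), profile)
  if (aa$qend < nchar(seq) && aa$rend == nchar(cons$seq))
    profile <- cbind(profile, profile_from_seq(
      substr(seq, aa$qend + 1L, nchar(seq))))
  if (length(newcols)) {
    shift <- if (aa$qstart > 1L && aa$rstart == 1L) aa$qstart - 1L else 0L
    for (nc in rev(newcols)) {
      at <- nc$after + shift
      profile <- cbind(profile[, seq_len(at), drop = FALSE], nc$col,
                       profile[, seq.int(at + 1L, ncol(profile)), drop = FALSE])
    }
  }
  profile
}

## stitch a set of oriented contig sequences, ordered by reference position,
## into a voted consensus; unplaceable neighbours are concatenated with a
## zero-length-gap flag
stitch_sequences <- function(seqs, min_overlap = 20L,
                             min_overlap_identity = 0.95) {
  stopifnot(length(seqs) >= 1L)
  profile <- profile_from_seq(seqs[[1L]])
  gap_cols <- integer(0)
  for (s in seqs[-1L]) {
    upd <- profile_overlay(profile, s, min_overlap, min_overlap_identity)
    if (is.null(upd)) {
      gap_cols <- c(gap_cols, ncol(profile))
      profile <- cbind(profile, profile_from_seq(s))
    } else {
      profile <- upd
    }
  }
  cons <- profile_consensus(profile)
  list(sequence = cons$seq,
       gap_flags = match(gap_cols, cons$map),
       ambiguous = which(cons$map %in% cons$ambiguous))
}

#' Build the per-half consensus sequences and merge them into one genome
#'
#' Per half, placed contigs are stitched in reference order with per-column
#' vote-majority (the reference never votes; contig pairs that abut without a
#' shared column are concatenated and the position recorded as a zero-length
#' gap). The two half consensi are then merged across their overlap region,
#' the terminal redundancy of the circular molecule is trimmed, the sequence
#' is rotated to start at LSC base 1, and the quadripartite structure is
#' annotated with [detect_ir()].
#'
#' @param placements placement table from [place_contigs()].
#' @param contigs the `contig_set` the placements refer to.
#' @param scaffolds the `scaffold_pair` used for placement.
#' @param min_overlap_identity minimum identity of stitch/merge overlaps.
#' @param min_ir_len passed to [detect_ir()] for the final annotation.
#' @param ir_mismatch_tol tolerated IRa vs revcomp(IRb) mismatch fraction
#'   before a warning is raised.
#' @return a `consensus_genome`: list with `sequence`, `regions`,
#'   `junctions`, `gap_flags`, `ambiguous_sites`, `ir_mismatches`,
#'   `half_lengths`.
#' @export
consensus_and_merge <- function(placements, contigs, scaffolds,
                                min_overlap_identity = 0.95,
                                min_ir_len = 1000L,
                                ir_mismatch_tol = 0.001) {
  stopifnot(inherits(scaffolds, "scaffold_pair"))
  halves <- list()
  gap_flags <- integer(0); ambiguous <- integer(0)
  for (h in c("A", "B")) {
    pl <- placements[placements$scaffold == h, ]
    if (!nrow(pl))
      stop(sprintf("no placements on scaffold half %s", h), call. = FALSE)
    pl <- pl[order(pl$ref_start, -pl$aligned_len), ]
    seqs <- lapply(seq_len(nrow(pl)), function(i) {
      s <- contigs$sequence[match(pl$contig_id[i], contigs$id)]
      if (pl$strand[i] == "-") revcomp(s) else s
    })
    st <- stitch_sequences(seqs, min_overlap_identity = min_overlap_identity)
    halves[[h]] <- st
    gap_flags <- c(gap_flags, st$gap_flags)
    ambiguous <- c(ambiguous, st$ambiguous)
  }
  ## merge half B onto half A across the shared overlap
  merged <- stitch_sequences(list(halves$A$sequence, halves$B$sequence),
                             min_overlap = 30L,
                             min_overlap_identity = min_overlap_identity)
  if (length(merged$gap_flags))
    stop("scaffold halves failed to overlap-align", call. = FALSE)
  out <- circularise_and_annotate(merged$sequence, min_ir_len = min_ir_len,
                                  ir_mismatch_tol = ir_mismatch_tol)
  out$gap_flags <- gap_flags
  out$ambiguous_sites <- sort(unique(c(ambiguous, merged$ambiguous)))
  out$half_lengths <- c(A = nchar(halves$A$sequence),
                        B = nchar(halves$B$sequence))
  out
}

## trim the exact terminal repeat of the linearised circle, rotate so the
## LSC starts at base 1, and annotate regions/junctions
circularise_and_annotate <- function(seq, min_ir_len = 1000L,
                                     ir_mismatch_tol = 0.001,
                                     max_terminal_repeat = 1000L) {
  L0 <- nchar(seq)
  for (x in seq.int(min(max_terminal_repeat, L0 %/% 2L), 15L)) {
    if (substr(seq, 1L, x) == substr(seq, L0 - x + 1L, L0)) {
      seq <- substr(seq, 1L, L0 - x)
      break
    }
  }
  L <- nchar(seq)
  ## detect the IR on the doubled circle so wrapped copies are seen whole
  ann2 <- detect_ir(paste0(seq, seq), min_ir_len = min_ir_len,
                    max_len = L)
  if (!nrow(ann2$regions)) {
    return(structure(list(sequence = seq,
                          regions = empty_regions(), junctions = empty_junctions(),
                          gap_flags = integer(0), ambiguous_sites = integer(0),
                          ir_mismatches = NA_integer_),
                     class = "consensus_genome"))
  }
  reg <- ann2$regions
  lsc_start0 <- ((reg$start[reg$region == "LSC"] - 1L) %% L) + 1L
  rot <- paste0(substr(seq, lsc_start0, L), substr(seq, 1L, lsc_start0 - 1L))
  ann <- detect_ir(rot, min_ir_len = min_ir_len)
  reg <- ann$regions
  irb <- reg[reg$region == "IRb", ]; ira <- reg[reg$region == "IRa", ]
  mism <- if (nrow(irb)) {
    str_mismatches(substr(rot, irb$start, irb$end),
                   revcomp(substr(rot, ira$start, ira$end)))
  } else NA_integer_
  if (!is.na(mism) && mism > ir_mismatch_tol * (irb$end - irb$start + 1L))
    warning(sprintf("IRa and revcomp(IRb) differ at %d positions", mism))
  structure(list(sequence = rot, regions = reg, junctions = ann$junctions,
                 gap_flags = integer(0), ambiguous_sites = integer(0),
                 ir_mismatches = mism),
            class = "consensus_genome")
}

#' @export
print.consensus_genome <- function(x, ...) {
  cat(sprintf("<consensus_genome> %s bp", format(nchar(x$sequence), big.mark = ",")))
  if (nrow(x$regions)) {
    rl <- x$regions$end - x$regions$start + 1L
    cat(sprintf(" | %s", paste(sprintf("%s %s", x$regions$region,
                                       format(rl, big.mark = ",")), collapse = " | ")))
  }
  cat(sprintf("\n  zero-length gaps: %d; ambiguous columns: %d\n",
              length(x$gap_flags), length(x$ambiguous_sites)))
  invisible(x)
}

empty_regions <- function() {
  data.frame(region = character(0), start = integer(0), end = integer(0))
}
empty_junctions <- function() {
  data.frame(junction = character(0), left = integer(0), right = integer(0))
}

#' Detect the inverted repeat pair in a plastome sequence
#'
#' Finds the maximal pair of disjoint intervals whose sequences are reverse
#' complements of each other (allowing up to `mismatch_tol` mismatches via
#' collinear run joining) and at least `min_ir_len` long, then labels the
#' longer inter-IR region LSC and the shorter SSC and reports the four
#' junction coordinates. Positions are 1-based; a junction between the
#' sequence end and base 1 reflects the circular molecule.
#'
#' @param sequence DNA string.
#' @param min_ir_len minimum IR length to report.
#' @param word_len exact seed width used in the scan.
#' @param mismatch_tol tolerated mismatch fraction when joining collinear
#'   exact runs into one repeat.
#' @param max_len restrict reported intervals to start within the first
#'   `max_len` bases (used internally for doubled-circle detection).
#' @return list with `regions` (LSC/IRb/SSC/IRa data.frame; empty when no IR
#'   qualifies) and `junctions` (`junction`, `left`, `right`).
#' @export
detect_ir <- function(sequence, min_ir_len = 1000L, word_len = 24L,
                      mismatch_tol = 0.001, max_len = NULL) {
  L <- nchar(sequence)
  if (L <= 2L * min_ir_len)
    stop("sequence must be longer than twice min_ir_len", call. = FALSE)
  w <- min(as.integer(word_len), as.integer(min_ir_len))
  rc <- revcomp(sequence)
  sw <- seq_words(sequence, w)
  rw <- seq_words(rc, w)
  setkey(rw, word)
  mm <- rw[sw, on = "word", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(mm)) return(list(regions = empty_regions(),
                             junctions = empty_junctions()))
  setnames(mm, c("pos", "i.pos"), c("jpos", "ipos"))
  ## s-vs-revcomp(s) matches lie on ordinary diagonals d = j - i
  mm[, diag0 := jpos - ipos]
  setorder(mm, diag0, ipos)
  mm[, run := cumsum(c(1L, diff(ipos) != 1L | diff(diag0) != 0L))]
  runs <- mm[, .(is = min(ipos), ie = max(ipos) + w - 1L,
                 diag0 = diag0[1]), by = run]
  ## join collinear runs separated by few mismatches
  cands <- list()
  for (d in unique(runs$diag0)) {
    rr <- runs[diag0 == d][order(is)]
    i <- 1L
    while (i <= nrow(rr)) {
      is0 <- rr$is[i]; ie0 <- rr$ie[i]; mis <- 0L
      j <- i + 1L
      while (j <= nrow(rr)) {
        gap_mis <- (rr$is[j] - ie0 - 1L) - w + 1L
        if (gap_mis < 0L) gap_mis <- 0L
        new_len <- rr$ie[j] - is0 + 1L
        if ((mis + gap_mis) / new_len > mismatch_tol) break
        mis <- mis + gap_mis; ie0 <- rr$ie[j]; j <- j + 1L
      }
      cands[[length(cands) + 1L]] <- data.table(
        is = is0, ie = ie0, diag0 = d, mism = mis)
      i <- j
    }
  }
  cand <- rbindlist(cands)
  ## revcomp coordinates of the run, then its mirror interval in `sequence`
  cand[, `:=`(js = is + diag0, je = ie + diag0)]
  cand[, `:=`(m1 = L - je + 1L, m2 = L - js + 1L)]
  cand[, len := ie - is + 1L]
  cand <- cand[len >= min_ir_len]
  ## forward-first disjoint pairs only (dedupes the mirrored duplicate and
  ## drops self-overlapping palindromes)
  cand <- cand[m1 > ie]
  if (!is.null(max_len)) cand <- cand[is <= max_len]
  if (!nrow(cand)) return(list(regions = empty_regions(),
                               junctions = empty_junctions()))
  ## ties (doubled-circle duplicates): prefer the nearest downstream mirror
  best <- cand[order(-len, is, m1)][1L]
  i1 <- c(best$is, best$ie); i2 <- c(best$m1, best$m2)
  ## polish: base-level maximal extension beyond the word resolution
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  while (i1[2] + 1L < i2[1] &&
         substr(sequence, i1[2] + 1L, i1[2] + 1L) ==
         comp1(substr(sequence, i2[1] - 1L, i2[1] - 1L))) {
    i1[2] <- i1[2] + 1L; i2[1] <- i2[1] - 1L
  }
  while (i1[1] > 1L && i2[2] < L &&
         substr(sequence, i1[1] - 1L, i1[1] - 1L) ==
         comp1(substr(sequence, i2[2] + 1L, i2[2] + 1L))) {
    i1[1] <- i1[1] - 1L; i2[2] <- i2[2] + 1L
  }
  Lc <- if (!is.null(max_len)) max_len else L
  annotate_quadripartite(i1, i2, Lc)
}

## label regions/junctions given the two IR intervals on a (possibly doubled)
## circle of length L; intervals are reported mod L
annotate_quadripartite <- function(i1, i2, L) {
  modp <- function(x) ((x - 1L) %% L) + 1L
  ir_len <- i1[2] - i1[1] + 1L
  mid_len <- i2[1] - i1[2] - 1L                 # between IR1 end and IR2 start
  out_len <- L - 2L * ir_len - mid_len          # circular complement
  if (out_len >= mid_len) {
    ## outer region is the LSC; IRb is the copy that follows it (= IR1)
    lsc <- c(modp(i2[2] + 1L), modp(i1[1] - 1L))
    irb <- i1; ssc <- c(i1[2] + 1L, i2[1] - 1L); ira <- i2
  } else {
    lsc <- c(i1[2] + 1L, i2[1] - 1L)
    irb <- i2; ssc <- c(modp(i2[2] + 1L), modp(i1[1] - 1L)); ira <- i1
  }
  regions <- data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = modp(c(lsc[1], irb[1], ssc[1], ira[1])),
    end = modp(c(lsc[2], irb[2], ssc[2], ira[2])))
  junctions <- data.frame(
    junction = c("J(LSC,IRb)", "J(IRb,SSC)", "J(SSC,IRa)", "J(IRa,LSC)"),
    left = c(regions$end[1], regions$end[2], regions$end[3], regions$end[4]),
    right = c(regions$start[2], regions$start[3], regions$start[4],
              regions$start[1]))
  list(regions = regions, junctions = junctions)
}

#' Write the quadripartite region annotation as GFF3 and the junctions as BED
#'
#' @param consensus a `consensus_genome`.
#' @param gff3_path,bed_path output paths (either may be `NULL` to skip).
#' @param seqname sequence name used in the outputs.
#' @return invisibly, the written paths.
#' @export
write_region_annotation <- function(consensus, gff3_path = NULL,
                                    bed_path = NULL,
                                    seqname = "consensus") {
  paths <- character(0)
  if (!is.null(gff3_path) && nrow(consensus$regions)) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = consensus$regions$start,
                                end = consensus$regions$end),
      type = "region", ID = consensus$regions$region,
      Name = consensus$regions$region)
    rtracklayer::export(gr, gff3_path, format = "gff3")
    paths <- c(paths, gff3_path)
  }
  if (!is.null(bed_path) && nrow(consensus$junctions)) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = consensus$junctions$left,
                                width = 1L),
      name = consensus$junctions$junction)
    rtracklayer::export(gr, bed_path, format = "bed")
    paths <- c(paths, bed_path)
  }
  invisible(paths)
}
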