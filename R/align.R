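## Anchor-chain alignment: exact-word anchors on one dominant diagonal band,
## chained left-to-right, with small gaps filled by Needleman-Wunsch
## (Biostrings::pairwiseAlignment). Used for contig placement on a diverged
## reference, for consensus stitching, and for whole-sequence identity.

nuc_submat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

pw_align <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = type, substitutionMatrix = nuc_submat(),
    gapOpening = 5, gapExtension = 2)
}

aligned_match_count <- function(p, s) {
  pc <- charToRaw(p); sc <- charToRaw(s)
  sum(pc == sc & pc != charToRaw("-"))
}

## maximal exact-match runs between query and ref on each diagonal
word_runs <- function(query, ref, word_len) {
  qw <- seq_words(query, word_len)
  rw <- seq_words(ref, word_len)
  setkey(rw, word)
  mm <- rw[qw, on = "word", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(mm)) return(data.table())
  setnames(mm, c("pos", "i.pos"), c("rpos", "qpos"))
  mm[, diag0 := rpos - qpos]
  setorder(mm, diag0, qpos)
  mm[, run := cumsum(c(1L, diff(qpos) != 1L | diff(diag0) != 0L))]
  runs <- mm[, .(qs = min(qpos), qe = max(qpos) + word_len - 1L,
                 rs = min(rpos), re = max(rpos) + word_len - 1L,
                 diag0 = diag0[1]), by = run]
  runs[, len := qe - qs + 1L]
  runs
}

#' Align a query sequence to a reference by anchor chaining
#'
#' Finds exact `word_len`-mer anchors, keeps those within `band` of the
#' dominant diagonal, chains them left to right, and fills inter-anchor gaps
#' with a gapped Needleman-Wunsch alignment. Intended for sequences that
#' share one collinear homologous segment (a contig against a scaffold
#' reference, or two assemblies of the same genome).
#'
#' @param query,ref DNA strings.
#' @param word_len exact anchor width.
#' @param band maximum diagonal drift from the dominant anchor, in bp.
#' @param max_fill largest inter-anchor gap that will be aligned; a larger
#'   gap aborts the alignment (`found = FALSE`).
#' @param extend_ends also align the unanchored query head/tail against the
#'   flanking reference sequence (bases that run off the reference end are
#'   reported as overhangs instead).
#' @param end_pad extra reference slack allowed in end extensions.
#' @return list with `found`, `qstart`, `qend`, `rstart`, `rend` (1-based
#'   inclusive coordinates of the aligned core), `matches`, `alen` (aligned
#'   columns), `pattern`/`subject` (gapped aligned strings, query first),
#'   `overhang_left`, `overhang_right` (query bases beyond the reference).
#' @export
anchor_align <- function(query, ref, word_len = 15L, band = 3000L,
                         max_fill = 5000L, extend_ends = TRUE,
                         end_pad = 30L) {
  failed <- list(found = FALSE, qstart = NA_integer_, qend = NA_integer_,
                 rstart = NA_integer_, rend = NA_integer_, matches = 0L,
                 alen = 0L, pattern = "", subject = "",
                 overhang_left = 0L, overhang_right = 0L)
  if (!nchar(query) || !nchar(ref)) return(failed)
  runs <- word_runs(query, ref, word_len)
  if (!nrow(runs)) return(failed)
  main_diag <- runs$diag0[which.max(runs$len)]
  runs <- runs[abs(diag0 - main_diag) <= band]
  setorder(runs, qs, rs)

  ## scored collinear chaining: anchored bases minus gap and diagonal-drift
  ## penalties, so chance off-diagonal word hits are not chained in
  n <- nrow(runs)
  dp <- as.numeric(runs$len); par <- integer(n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in (i - 1L):1L) {
        if (runs$qs[j] >= runs$qs[i] || runs$rs[j] >= runs$rs[i] ||
            runs$qe[j] >= runs$qe[i] || runs$re[j] >= runs$re[i]) next
        qg <- runs$qs[i] - runs$qe[j] - 1L
        rg <- runs$rs[i] - runs$re[j] - 1L
        if (max(qg, rg) > max_fill) next
        drift <- abs(runs$diag0[i] - runs$diag0[j])
        cand <- dp[j] + runs$len[i] - 0.01 * max(0L, max(qg, rg)) -
          0.5 * drift
        if (cand > dp[i]) { dp[i] <- cand; par[i] <- j }
      }
    }
  }
  idx <- which.max(dp)
  path <- integer(0)
  while (idx > 0L) { path <- c(idx, path); idx <- par[idx] }
  runs <- runs[path]

  ## trim residual overlaps between consecutive chained runs
  chain <- list(); last_qe <- 0L; last_re <- 0L
  for (i in seq_len(nrow(runs))) {
    r <- as.list(runs[i])
    dq <- last_qe - r$qs + 1L
    if (dq > 0L) { r$qs <- r$qs + dq; r$rs <- r$rs + dq }
    dr <- last_re - r$rs + 1L
    if (dr > 0L) { r$qs <- r$qs + dr; r$rs <- r$rs + dr }
    if (r$qs > r$qe || r$rs > r$re) next
    chain[[length(chain) + 1L]] <- r
    last_qe <- r$qe; last_re <- r$re
  }
  if (!length(chain)) return(failed)

  pat <- character(0); sub <- character(0); matches <- 0L
  for (i in seq_along(chain)) {
    r <- chain[[i]]
    if (i > 1L) {
      p <- chain[[i - 1L]]
      qgap <- r$qs - p$qe - 1L; rgap <- r$rs - p$re - 1L
      if (qgap > max_fill || rgap > max_fill) return(failed)
      if (qgap > 0L || rgap > 0L) {
        qg <- substr(query, p$qe + 1L, r$qs - 1L)
        rg <- substr(ref, p$re + 1L, r$rs - 1L)
        if (qgap == 0L) {
          pat <- c(pat, strrep("-", rgap)); sub <- c(sub, rg)
        } else if (rgap == 0L) {
          pat <- c(pat, qg); sub <- c(sub, strrep("-", qgap))
        } else {
          al <- pw_align(qg, rg, type = "global")
          pa <- as.character(Biostrings::alignedPattern(al))
          sa <- as.character(Biostrings::alignedSubject(al))
          matches <- matches + aligned_match_count(pa, sa)
          pat <- c(pat, pa); sub <- c(sub, sa)
        }
      }
    }
    piece <- substr(query, r$qs, r$qe)
    pat <- c(pat, piece); sub <- c(sub, piece)
    matches <- matches + nchar(piece)
  }
  first <- chain[[1L]]; last <- chain[[length(chain)]]
  qstart <- first$qs; qend <- last$qe
  rstart <- first$rs; rend <- last$re
  ohl <- 0L; ohr <- 0L

  if (extend_ends && qstart > 1L) {
    headlen <- qstart - 1L
    avail <- rstart - 1L
    alignable <- min(headlen, avail)
    ohl <- headlen - alignable
    if (alignable > 0L) {
      qh <- substr(query, qstart - alignable, qstart - 1L)
      rwin_s <- max(1L, rstart - alignable - end_pad)
      rh <- substr(ref, rwin_s, rstart - 1L)
      al <- pw_align(qh, rh, type = "global-local")
      pa <- as.character(Biostrings::alignedPattern(al))
      sa <- as.character(Biostrings::alignedSubject(al))
      matches <- matches + aligned_match_count(pa, sa)
      pat <- c(pa, pat); sub <- c(sa, sub)
      qstart <- qstart - alignable
      rstart <- rwin_s + Biostrings::start(Biostrings::subject(al)) - 1L
    }
  }
  if (extend_ends && qend < nchar(query)) {
    taillen <- nchar(query) - qend
    avail <- nchar(ref) - rend
    alignable <- min(taillen, avail)
    ohr <- taillen - alignable
    if (alignable > 0L) {
      qt <- substr(query, qend + 1L, qend + alignable)
      rt <- substr(ref, rend + 1L, min(nchar(ref), rend + alignable + end_pad))
      al <- pw_align(qt, rt, type = "global-local")
      pa <- as.character(Biostrings::alignedPattern(al))
      sa <- as.character(Biostrings::alignedSubject(al))
      matches <- matches + aligned_match_count(pa, sa)
      pat <- c(pat, pa); sub <- c(sub, sa)
      qend <- qend + alignable
      rend <- rend + Biostrings::end(Biostrings::subject(al))
    }
  }
  pattern <- paste(pat, collapse = "")
  list(found = TRUE, qstart = qstart, qend = qend, rstart = rstart,
       rend = rend, matches = matches, alen = nchar(pattern),
       pattern = pattern, subject = paste(sub, collapse = ""),
       overhang_left = ohl, overhang_right = ohr)
}

#' Fraction of identical aligned bases between two homologous sequences
#'
#' Identical strings score 1 directly; otherwise the sequences are aligned
#' with [anchor_align()] and identity is matches over the longer length.
#'
#' @param a,b DNA strings.
#' @return identity in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  aa <- anchor_align(a, b, word_len = 15L)
  if (!aa$found) return(0)
  aa$matches / max(nchar(a), nchar(b))
}

#' Identity between two circular sequences, best over rotations
#'
#' For equal-length sequences, aligns the rotation of `a` that matches the
#' start of `b` (either strand) and counts identical positions; rotation
#' ambiguity arises naturally when a chance repeat extension shifts the
#' annotated LSC origin. Falls back to [sequence_identity()] when no
#' rotation anchor is found or lengths differ.
#'
#' @param a,b DNA strings.
#' @return identity in `[0, 1]`.
#' @export
circular_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) return(sequence_identity(a, b))
  if (sequences_equal_circular(a, b)) return(1)
  probe <- substr(b, 1L, min(60L, nchar(b)))
  for (cand in c(a, revcomp(a))) {
    p <- regexpr(probe, paste0(cand, cand), fixed = TRUE)
    if (p > 0L && p <= nchar(cand)) {
      rot <- circular_substr(cand, as.integer(p), nchar(cand))
      return(1 - str_mismatches(rot, b) / nchar(b))
    }
  }
  sequence_identity(a, b)
}

#' Are two sequences equal as circular molecules?
#'
#' Tests equality under rotation and reverse complement.
#'
#' @param a,b DNA strings.
#' @return `TRUE` or `FALSE`.
#' @export
sequences_equal_circular <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  grepl(b, paste0(a, a), fixed = TRUE) ||
    grepl(revcomp(b), paste0(a, a), fixed = TRUE)
}
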