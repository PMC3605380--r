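## readprep: quality trimming (modified-Mott running sum), length filtering
## and deterministic every-nth subsampling of paired reads.

#' Phred score equivalent of an error probability
#'
#' `floor(-10 * log10(p))`; e.g. a quality limit of 0.05 corresponds to a
#' minimum Phred score of 13.
#'
#' @param p error probability in `(0, 1]`.
#' @return integer Phred score.
#' @export
#' @examples
#' phred_from_prob(0.05)  # 13
phred_from_prob <- function(p) {
  stop_if_not_scalar_number(p, "p")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]", call. = FALSE)
  as.integer(floor(-10 * log10(p) + 1e-9))
}

#' Trimming configuration
#'
#' @param quality_limit error-probability limit for the running-sum trimmer.
#'   The limit is quantised to its integer Phred equivalent
#'   ([phred_from_prob()]), so 0.05 behaves exactly as "Phred >= 13".
#' @param min_len minimum post-trim read length in bp; shorter reads are
#'   rejected.
#' @return a `trim_config` list.
#' @export
trim_config <- function(quality_limit = 0.05, min_len = 50L) {
  if (quality_limit <= 0 || quality_limit >= 1)
    stop("quality_limit must lie in (0, 1)", call. = FALSE)
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  structure(list(quality_limit = quality_limit, min_len = as.integer(min_len)),
            class = "trim_config")
}

## per-base scores for the modified-Mott trimmer: p_limit - p_base, with the
## limit quantised to integer Phred so boundary qualities score exactly zero
mott_scores <- function(qual, quality_limit) {
  q <- utf8ToInt(qual) - 33L
  p_limit <- 10^(-phred_from_prob(quality_limit) / 10)
  p_limit - 10^(-q / 10)
}

## maximal-sum segment, ties resolved leftmost start then longest extent.
## Returns c(start, end) or c(0, -1) when every segment sums negative.
max_sum_segment <- function(s) {
  n <- length(s)
  cs <- c(0, cumsum(s))
  eps <- 1e-12
  best <- -Inf; bs <- 0L; be <- -1L
  minv <- 0; mini <- 0L
  for (e in seq_len(n)) {
    cand <- cs[e + 1L] - minv
    if (cand > best + eps ||
        (cand > best - eps && (mini + 1L < bs ||
                               (mini + 1L == bs && e > be)))) {
      best <- max(best, cand); bs <- mini + 1L; be <- e
    }
    if (cs[e + 1L] < minv - eps) { minv <- cs[e + 1L]; mini <- e }
  }
  if (best < -eps) c(0L, -1L) else c(bs, be)
}

#' Quality-trim a single read
#'
#' Modified-Mott running-sum trimming: each base scores
#' `p_limit - p(base)` and the retained segment is the maximal-sum window
#' (leftmost, then longest, on ties). Reads whose best window sums negative
#' or falls below `min_len` are rejected.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string of the same length.
#' @param config a [trim_config()].
#' @return list with `seq`, `qual`, `start`, `end`, or `NULL` if rejected.
#' @export
trim_read <- function(seq, qual, config = trim_config()) {
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality strings differ in length", call. = FALSE)
  seg <- max_sum_segment(mott_scores(qual, config$quality_limit))
  len <- seg[2] - seg[1] + 1L
  if (len < config$min_len) return(NULL)
  list(seq = substr(seq, seg[1], seg[2]), qual = substr(qual, seg[1], seg[2]),
       start = seg[1], end = seg[2])
}

#' Quality-trim paired reads
#'
#' Applies [trim_read()] to both mates of every pair; a pair is kept only if
#' both mates survive, so mate files stay synchronised.
#'
#' @param rp a `read_pairs` object.
#' @param config a [trim_config()].
#' @return a trimmed `read_pairs` object; the number of pairs removed is
#'   available as `attr(, "n_rejected_pairs")`.
#' @export
trim_pairs <- function(rp, config = trim_config()) {
  t1 <- lapply(seq_along(rp$id), function(i) trim_read(rp$r1[i], rp$q1[i], config))
  t2 <- lapply(seq_along(rp$id), function(i) trim_read(rp$r2[i], rp$q2[i], config))
  keep <- !vapply(t1, is.null, TRUE) & !vapply(t2, is.null, TRUE)
  out <- rp
  out$id <- rp$id[keep]
  out$r1 <- vapply(t1[keep], `[[`, "", "seq")
  out$q1 <- vapply(t1[keep], `[[`, "", "qual")
  out$r2 <- vapply(t2[keep], `[[`, "", "seq")
  out$q2 <- vapply(t2[keep], `[[`, "", "qual")
  if (!is.null(rp$truth)) out$truth <- rp$truth[keep]
  attr(out, "n_rejected_pairs") <- sum(!keep)
  out
}

#' Keep every n-th read pair
#'
#' Deterministic subsampling: pairs at 0-based indices `0, n, 2n, ...` are
#' kept (the first pair always survives), and mates stay synchronised.
#' `n = 2, 4, 8` keep 50%, 25% and 12.5% of the pairs.
#'
#' @param rp a `read_pairs` object.
#' @param n keep-every-nth step, `>= 1`.
#' @return a subsampled `read_pairs` object.
#' @export
subsample_every_nth <- function(rp, n) {
  stop_if_not_scalar_number(n, "n")
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  idx <- seq.int(1L, length(rp$id), by = as.integer(n))
  out <- rp
  for (f in c("id", "r1", "r2", "q1", "q2")) out[[f]] <- rp[[f]][idx]
  if (!is.null(rp$truth)) out$truth <- rp$truth[idx]
  out
}

#' Summary statistics of a read set
#'
#' @param rp a `read_pairs` object.
#' @return data.frame with `n_reads` (both mates counted), `mean_len` and
#'   `mean_phred`.
#' @export
read_stats <- function(rp) {
  seqs <- c(rp$r1, rp$r2)
  quals <- c(rp$q1, rp$q2)
  mean_q <- if (length(quals)) {
    mean(unlist(lapply(quals, function(q) utf8ToInt(q) - 33L)))
  } else 0
  data.frame(n_reads = length(seqs),
             mean_len = if (length(seqs)) mean(nchar(seqs)) else 0,
             mean_phred = mean_q)
}
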