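# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (enumeration, O(n^2) scans) so they share no code path
# with the implementation they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# exhaustive maximal-sum segment: leftmost start, then longest, on ties
oracle_max_segment <- function(s) {
  n <- length(s)
  best <- -Inf; bs <- 0L; be <- -1L
  for (i in seq_len(n)) for (j in i:n) {
    v <- sum(s[i:j])
    if (v > best + 1e-12 ||
        (v > best - 1e-12 && (i < bs || (i == bs && j > be)))) {
      best <- max(best, v); bs <- i; be <- j
    }
  }
  if (best < -1e-12) c(0L, -1L) else c(bs, be)
}

# best ungapped local alignment score over all offsets and strands
oracle_local_score <- function(a, b, match = 1, mismatch = -2) {
  best <- 0
  for (bb in c(b, revcomp(b))) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(bb, "")[[1]]
    m <- length(ca); n <- length(cb)
    for (d in (-(m - 1)):(n - 1)) {
      lo <- max(1, 1 - d); hi <- min(m, n - d)
      if (hi < lo) next
      s <- ifelse(ca[lo:hi] == cb[(lo + d):(hi + d)], match, mismatch)
      cur <- 0
      for (x in s) {
        cur <- max(0, cur + x)
        best <- max(best, cur)
      }
    }
  }
  best
}

# exhaustive maximal disjoint reverse-complement interval pair
oracle_ir <- function(s, min_len) {
  L <- nchar(s)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(revcomp(s), "")[[1]]
  best <- NULL
  for (d in (-(L - 1)):(L - 1)) {
    ilo <- max(1, 1 - d); ihi <- min(L, L - d)
    if (ihi < ilo) next
    eq <- a[ilo:ihi] == b[(ilo + d):(ihi + d)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_len)) {
      is <- ilo + starts[k] - 1; ie <- ilo + ends[k] - 1
      js <- is + d; je <- ie + d
      m1 <- L - je + 1; m2 <- L - js + 1
      if (m1 > ie && (is.null(best) || (ie - is) > (best[2] - best[1])))
        best <- c(is, ie, m1, m2)
    }
  }
  best
}

# literal two-threshold scan over a pileup table
oracle_call_snps <- function(pile, mvf, min_cov) {
  out <- list()
  for (i in seq_len(nrow(pile))) {
    row <- pile[i, ]
    if (row$depth < min_cov) next
    for (b in c("A", "C", "G", "T")) {
      if (b == row$ref) next
      cnt <- row[[b]]
      if (cnt > 0 && cnt / row$depth >= mvf)
        out[[length(out) + 1L]] <- data.frame(pos = row$pos, alt = b,
                                              frequency = cnt / row$depth)
    }
  }
  if (!length(out)) return(data.frame(pos = integer(0), alt = character(0),
                                      frequency = numeric(0)))
  do.call(rbind, out)
}

oracle_n50 <- function(lengths) {
  l <- sort(lengths, decreasing = TRUE)
  tot <- sum(l)
  run <- 0
  for (x in l) {
    run <- run + x
    if (run >= tot / 2) return(x)
  }
}

# error-free sliding-window reads from a linear sequence (both strands)
reads_from_linear <- function(seq, read_len = 100L, step = 4L) {
  n <- nchar(seq)
  starts <- seq(1L, n - read_len + 1L, by = step)
  fwd <- substring(seq, starts, starts + read_len - 1L)
  c(fwd, revcomp(fwd))
}

# a small quadripartite fixture shared by scaffolder/pipeline tests
tiny_fixture <- function(seed = 31L, n_pairs = 900L, per_base_error = 0) {
  g <- make_genome(3500, 900, 1000, seed = seed)
  ref <- diverge(g, 0.10, 0.005, seed = seed + 1L)
  rp <- simulate_reads(make_pool(g, 1L, list()), sim_config(
    n_pairs = n_pairs, cp_fraction = 1, per_base_error = per_base_error,
    seed = seed + 2L))
  list(genome = g, truth = genome_sequence(g), reference = ref, reads = rp)
}
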