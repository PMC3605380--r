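## cpbin: classify contigs as chloroplast by ungapped seed-and-extend local
## alignment against a plastome database, scored with Karlin-Altschul
## statistics. The "E-value of zero" filter is operationalised as
## E <= 1e-180 (the double-precision proxy for a printed 0.0).

#' Karlin-Altschul parameters for an ungapped match/mismatch scheme
#'
#' `lambda` is the positive root of `sum(p_i p_j exp(lambda * s_ij)) = 1`
#' under a uniform base composition; `K` is computed from the classical
#' lattice-score series (k-fold convolutions of the step distribution).
#'
#' @param match,mismatch alignment scores (`match > 0 > mismatch`, integers).
#' @param p base composition (defaults uniform).
#' @return list with `lambda`, `K` and `H` (relative entropy, nats).
#' @export
#' @examples
#' karlin_altschul(1, -2)  # lambda ~ 1.33, K ~ 0.62
karlin_altschul <- function(match, mismatch, p = rep(0.25, 4)) {
  if (!(match > 0 && mismatch < 0))
    stop("scores must satisfy match > 0 > mismatch", call. = FALSE)
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  p_match <- sum(p^2)
  p_mis <- 1 - p_match
  ## step-score distribution on the integer lattice
  lo <- mismatch; hi <- match
  probs <- numeric(hi - lo + 1L)
  probs[match - lo + 1L] <- p_match
  probs[1L] <- probs[1L] + p_mis
  scores <- lo:hi
  if (sum(probs * scores) >= 0)
    stop("expected step score must be negative", call. = FALSE)
  delta <- Reduce(gcd2, abs(scores[probs > 0]))

  f <- function(l) sum(probs * exp(l * scores)) - 1
  hi_l <- 1
  while (f(hi_l) < 0) hi_l <- hi_l * 2
  lambda <- uniroot(f, c(1e-8, hi_l), tol = 1e-12)$root

  ## C = sum_k (1/k) [ E(e^{lambda S_k}; S_k < 0) + P(S_k >= 0) ]
  C <- 0
  conv <- probs
  conv_scores <- scores
  for (k in 1:60) {
    neg <- conv_scores < 0
    term <- sum(conv[neg] * exp(lambda * conv_scores[neg])) +
      sum(conv[!neg])
    C <- C + term / k
    if (term / k < 1e-12) break
    res <- convolve_lattice(conv, conv_scores, probs, scores)
    conv <- res$probs; conv_scores <- res$scores
  }
  Es <- sum(probs * scores * exp(lambda * scores))
  K <- delta * exp(-2 * C) / ((1 - exp(-lambda * delta)) * Es)
  H <- lambda * Es
  list(lambda = lambda, K = K, H = H)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

convolve_lattice <- function(pa, sa, pb, sb) {
  smin <- min(sa) + min(sb); smax <- max(sa) + max(sb)
  out <- numeric(smax - smin + 1L)
  for (i in seq_along(pa)) {
    if (pa[i] == 0) next
    idx <- (sa[i] + sb) - smin + 1L
    out[idx] <- out[idx] + pa[i] * pb
  }
  list(probs = out, scores = smin:smax)
}

#' E-value of an ungapped local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`, evaluated in log space so very strong
#' scores underflow cleanly to 0.
#'
#' @param score alignment raw score.
#' @param m,n query and database sequence lengths.
#' @param ka parameters from [karlin_altschul()].
#' @return the expected number of chance alignments at least this good.
#' @export
evalue <- function(score, m, n, ka) {
  exp(log(ka$K) + log(m) + log(n) - ka$lambda * score)
}

bitscore <- function(score, ka) (ka$lambda * score - log(ka$K)) / log(2)

#' Seed-and-extend ungapped local alignment of a contig against a genome
#'
#' Exact `word_len`-mers seed both strands; each seed is extended without
#' gaps under an X-drop rule; overlapping hits on the same diagonal are
#' reported once (best scoring). E-values follow [karlin_altschul()]
#' statistics for the chosen scores.
#'
#' @param contig query DNA string.
#' @param db_genome database DNA string.
#' @param db_id,contig_id labels carried into the hit table.
#' @param word_len exact seed width (`>= 4`).
#' @param match,mismatch alignment scores.
#' @param xdrop score drop-off that terminates extension.
#' @param ka optional precomputed [karlin_altschul()] parameters.
#' @return data.table of hits: `contig_id`, `db_id`, `score`, `bitscore`,
#'   `evalue`, `contig_start`, `contig_end`, `db_start`, `db_end`, `strand`
#'   (contig coordinates always on the + contig).
#' @export
seed_extend <- function(contig, db_genome, db_id = "db", contig_id = "contig",
                        word_len = 11L, match = 1L, mismatch = -2L,
                        xdrop = 20L, ka = NULL) {
  if (!nchar(contig) || !nchar(db_genome))
    stop("empty sequences", call. = FALSE)
  if (word_len < 4L) stop("word_len must be >= 4", call. = FALSE)
  if (!(match > 0 && mismatch < 0))
    stop("scores must satisfy match > 0 > mismatch", call. = FALSE)
  if (is.null(ka)) ka <- karlin_altschul(match, mismatch)
  m <- nchar(contig); n <- nchar(db_genome)
  dbw <- seq_words(db_genome, word_len)
  setkey(dbw, word)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") contig else revcomp(contig)
    qw <- seq_words(q, word_len)
    mm <- dbw[qw, on = "word", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(mm)) next
    setnames(mm, c("pos", "i.pos"), c("dbpos", "qpos"))
    mm[, diag0 := dbpos - qpos]
    setorder(mm, diag0, qpos)
    for (d in unique(mm$diag0)) {
      seeds <- mm[diag0 == d]
      ## overlapping region of query and db on this diagonal
      qlo <- max(1L, 1L - d); qhi <- min(m, n - d)
      qs <- substr(q, qlo, qhi)
      ds <- substr(db_genome, qlo + d, qhi + d)
      eq <- charToRaw(qs) == charToRaw(ds)
      sc <- ifelse(eq, match, mismatch)
      covered_hi <- 0L
      for (sp in seeds$qpos) {
        if (sp <= covered_hi) next
        ext <- xdrop_extend(sc, sp - qlo + 1L, word_len, xdrop)
        q1 <- ext$from + qlo - 1L; q2 <- ext$to + qlo - 1L
        covered_hi <- q2
        cs <- if (strand == "+") c(q1, q2) else c(m - q2 + 1L, m - q1 + 1L)
        hits[[length(hits) + 1L]] <- data.table(
          contig_id = contig_id, db_id = db_id, score = ext$score,
          contig_start = cs[1], contig_end = cs[2],
          db_start = q1 + d, db_end = q2 + d, strand = strand)
      }
    }
  }
  if (!length(hits))
    return(data.table(contig_id = character(0), db_id = character(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), contig_start = integer(0),
                      contig_end = integer(0), db_start = integer(0),
                      db_end = integer(0), strand = character(0)))
  out <- rbindlist(hits)
  out[, `:=`(bitscore = bitscore(score, ka), evalue = evalue(score, m, n, ka))]
  setorder(out, -score, db_start)
  ## drop hits mostly contained in a better hit on the same strand
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ci <- out[i]
    dominated <- FALSE
    for (j in which(keep)) {
      cj <- out[j]
      if (cj$strand != ci$strand) next
      ov <- min(ci$contig_end, cj$contig_end) -
        max(ci$contig_start, cj$contig_start) + 1L
      if (ov > 0.5 * (ci$contig_end - ci$contig_start + 1L)) {
        dominated <- TRUE; break
      }
    }
    keep[i] <- !dominated
  }
  setcolorder(out[keep],
              c("contig_id", "db_id", "score", "bitscore", "evalue",
                "contig_start", "contig_end", "db_start", "db_end", "strand"))
}

## maximal X-drop extension of a seed [sp, sp+word_len-1] within score vector
xdrop_extend <- function(sc, sp, word_len, xdrop) {
  n <- length(sc)
  se <- sp + word_len - 1L
  seed_score <- sum(sc[sp:se])
  ## right extension
  rbest <- 0; rto <- se
  if (se < n) {
    cum <- cumsum(sc[(se + 1L):n])
    run <- cummax(cum)
    cut <- which(run - cum > xdrop)[1]
    lim <- if (is.na(cut)) length(cum) else cut
    if (lim >= 1L) {
      i <- which.max(cum[seq_len(lim)])
      if (cum[i] > 0) { rbest <- cum[i]; rto <- se + i }
    }
  }
  ## left extension
  lbest <- 0; lfrom <- sp
  if (sp > 1L) {
    cum <- cumsum(rev(sc[1:(sp - 1L)]))
    run <- cummax(cum)
    cut <- which(run - cum > xdrop)[1]
    lim <- if (is.na(cut)) length(cum) else cut
    if (lim >= 1L) {
      i <- which.max(cum[seq_len(lim)])
      if (cum[i] > 0) { lbest <- cum[i]; lfrom <- sp - i }
    }
  }
  list(score = seed_score + rbest + lbest, from = lfrom, to = rto)
}

#' Bin contigs as chloroplast by their best database hit
#'
#' A contig is kept when its best hit against any database genome has an
#' E-value at or below `evalue_max` (default `1e-180`, the operational
#' meaning of "E-value of zero").
#'
#' @param contigs a `contig_set`.
#' @param database named character vector of genome sequences, a
#'   `DNAStringSet`, or a multi-FASTA path.
#' @param evalue_max inclusion threshold.
#' @param ... passed to [seed_extend()].
#' @return list with `kept` (subset `contig_set`) and `hits` (best hit per
#'   contig, all contigs, `NA` E-value when no hit at all).
#' @export
bin_contigs <- function(contigs, database, evalue_max = 1e-180, ...) {
  db <- as_genome_vector(database)
  if (!length(db)) stop("database must be non-empty", call. = FALSE)
  if (!nrow(contigs))
    return(list(kept = contigs, hits = data.table(contig_id = character(0))))
  dots <- list(...)
  match <- if (is.null(dots$match)) 1L else dots$match
  mismatch <- if (is.null(dots$mismatch)) -2L else dots$mismatch
  ka <- karlin_altschul(match, mismatch)
  best <- lapply(seq_len(nrow(contigs)), function(i) {
    m <- nchar(contigs$sequence[i])
    h <- rbindlist(lapply(names(db), function(g) {
      seed_extend(contigs$sequence[i], db[[g]], db_id = g,
                  contig_id = contigs$id[i], ka = ka, ...)
    }))
    if (!nrow(h))
      return(data.table(contig_id = contigs$id[i], db_id = NA_character_,
                        score = NA_real_, bitscore = NA_real_,
                        evalue = NA_real_, contig_start = NA_integer_,
                        contig_end = NA_integer_, db_start = NA_integer_,
                        db_end = NA_integer_, strand = NA_character_))
    ## sum-score chaining: collinear non-overlapping HSPs against one genome
    ## and strand jointly determine the contig-level E-value
    top <- h[which.max(score)]
    chained <- h[, .(score = chain_hsp_score(.SD, strand == "+")),
                 by = .(db_id, strand)][which.max(score)]
    n_db <- nchar(db[[chained$db_id]])
    top$score <- chained$score
    top$bitscore <- bitscore(chained$score, ka)
    top$evalue <- evalue(chained$score, m, n_db, ka)
    top
  })
  hits <- rbindlist(best)
  kept_ids <- hits[!is.na(evalue) & evalue <= evalue_max, contig_id]
  list(kept = contigs[contigs$id %in% kept_ids, ], hits = hits)
}

## best total score over collinear non-overlapping chains of HSPs (DP)
chain_hsp_score <- function(h, fwd) {
  h <- h[order(contig_start)]
  n <- nrow(h)
  dp <- h$score
  for (i in seq_len(n)) {
    prev <- which(h$contig_end < h$contig_start[i] &
                    (if (fwd) h$db_end < h$db_start[i]
                     else h$db_start > h$db_end[i]))
    if (length(prev)) dp[i] <- h$score[i] + max(dp[prev])
  }
  max(dp)
}

as_genome_vector <- function(database) {
  if (is.character(database) && length(database) == 1L && file.exists(database))
    database <- Biostrings::readDNAStringSet(database)
  if (inherits(database, "DNAStringSet")) {
    out <- as.character(database)
    names(out) <- sub(" .*", "", names(database))
    return(as.list(out))
  }
  if (is.character(database)) {
    if (is.null(names(database)))
      names(database) <- sprintf("db%d", seq_along(database))
    return(as.list(database))
  }
  if (is.list(database)) return(database)
  stop("unsupported database type", call. = FALSE)
}

#' Write a homology hit table as TSV (BLAST outfmt-6 column spirit)
#' @param hits hit table from [bin_contigs()] or [seed_extend()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
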