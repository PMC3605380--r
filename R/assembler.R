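## assembler: de Bruijn unitig assembly. Nodes are (k-1)-mers, edges are
## k-mers observed in the reads (both strands are inserted, so the graph is
## strand-symmetric); unitigs are maximal non-branching edge paths, emitted
## once in canonical orientation.

#' Assemble reads into unitig contigs
#'
#' Builds the k-mer graph over the reads and their reverse complements,
#' optionally drops low-coverage k-mers, clips short dead-end tips, resolves
#' simple bubbles in favour of the higher-coverage branch, and emits maximal
#' non-branching paths as contigs.
#'
#' The automatic coverage cutoff follows a Velvet-style rule: k-mers observed
#' once are dropped when the mean k-mer coverage exceeds 10.
#'
#' @param reads a `read_pairs` object or character vector of read sequences.
#' @param k odd k-mer size, smaller than the read length.
#' @param min_contig_len minimum emitted contig length in bp.
#' @param cov_cutoff drop k-mers with coverage `< cov_cutoff`; `NULL` for the
#'   automatic rule.
#' @return a `contig_set` data.table with columns `id`, `sequence`, `length`,
#'   `k`, `mean_kmer_coverage`.
#' @export
assemble <- function(reads, k, min_contig_len = 200L, cov_cutoff = NULL) {
  seqs <- if (inherits(reads, "read_pairs")) c(reads$r1, reads$r2)
          else as.character(reads)
  if (!length(seqs)) stop("no reads supplied", call. = FALSE)
  stop_if_not_scalar_number(k, "k")
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  if (k >= max(nchar(seqs)))
    stop("k must be smaller than the read length", call. = FALSE)

  km <- data.table(kmer = seq_kmers(c(seqs, revcomp(seqs)), k))
  km <- km[, .(count = .N), by = kmer]
  if (is.null(cov_cutoff)) {
    if (mean(km$count) > 10) km <- km[count > 1L]
  } else {
    km <- km[count >= cov_cutoff]
  }
  if (!nrow(km)) return(empty_contig_set(k))
  setkey(km, kmer)  # deterministic order, independent of read order

  km <- clip_tips(km, k, rounds = 3L)
  km <- pop_bubbles(km, k)
  utg <- kmer_unitigs(km, k)
  if (!nrow(utg)) return(empty_contig_set(k))

  ## strand-symmetric graph: every unitig also appears as its reverse
  ## complement; keep the canonical copy once
  utg[, canon := canonical_seq(sequence)]
  utg <- utg[, .SD[which.max(mean_cov)], by = canon][, canon := NULL]
  utg <- utg[nchar(sequence) >= min_contig_len]
  setorder(utg, -mean_cov)
  setorder(utg, sequence)  # fully deterministic id assignment
  out <- data.table(
    id = sprintf("k%d_utg%04d", k, seq_len(nrow(utg))),
    sequence = utg$sequence,
    length = nchar(utg$sequence),
    k = k,
    mean_kmer_coverage = utg$mean_cov)
  class(out) <- c("contig_set", class(out))
  out[]
}

empty_contig_set <- function(k) {
  out <- data.table(id = character(0), sequence = character(0),
                    length = integer(0), k = integer(0),
                    mean_kmer_coverage = numeric(0))
  class(out) <- c("contig_set", class(out))
  out
}

## decompose the k-mer edge set into maximal non-branching paths
kmer_unitigs <- function(km, k) {
  n <- nrow(km)
  pref <- substr(km$kmer, 1L, k - 1L)
  suff <- substr(km$kmer, 2L, k)
  nodes <- data.table(node = c(pref, suff))[, .N, by = node]
  outdeg <- data.table(node = pref)[, .(outdeg = .N), by = node]
  indeg <- data.table(node = suff)[, .(indeg = .N), by = node]
  deg <- merge(outdeg, indeg, by = "node", all = TRUE)
  deg[is.na(outdeg), outdeg := 0L][is.na(indeg), indeg := 0L]
  setkey(deg, node)
  ## through-node: exactly one edge in, one edge out -> the path continues
  through <- deg[outdeg == 1L & indeg == 1L, node]
  ## successor edge index for edges whose suffix is a through-node
  pref_map <- data.table(node = pref, idx = seq_len(n), key = "node")
  nxt <- rep(NA_integer_, n)
  ok <- suff %chin% through
  if (any(ok)) nxt[ok] <- pref_map[J(suff[ok]), idx]
  prv <- rep(NA_integer_, n)
  suff_map <- data.table(node = suff, idx = seq_len(n), key = "node")
  okp <- pref %chin% through
  if (any(okp)) prv[okp] <- suff_map[J(pref[okp]), idx]

  visited <- logical(n)
  seqs <- character(0); covs <- numeric(0)
  starts <- which(is.na(prv))
  last_char <- substr(km$kmer, k, k)
  for (s in starts) {
    if (visited[s]) next
    chain <- integer(0); i <- s
    while (!is.na(i) && !visited[i]) {
      visited[i] <- TRUE
      chain <- c(chain, i)
      i <- nxt[i]
    }
    seqs <- c(seqs, paste0(km$kmer[chain[1]],
                           paste(last_char[chain[-1]], collapse = "")))
    covs <- c(covs, mean(km$count[chain]))
  }
  ## leftover edges belong to cycles (e.g. a repeat-free circular genome)
  for (s in which(!visited)) {
    if (visited[s]) next
    chain <- integer(0); i <- s
    while (!is.na(i) && !visited[i]) {
      visited[i] <- TRUE
      chain <- c(chain, i)
      i <- nxt[i]
    }
    seqs <- c(seqs, paste0(km$kmer[chain[1]],
                           paste(last_char[chain[-1]], collapse = "")))
    covs <- c(covs, mean(km$count[chain]))
  }
  data.table(sequence = seqs, mean_cov = covs)
}

## remove dead-end chains shorter than 2k that hang off a branching node
clip_tips <- function(km, k, rounds = 3L) {
  for (r in seq_len(rounds)) {
    utg <- kmer_unitigs_raw(km, k)
    if (!nrow(utg)) return(km)
    pref <- substr(km$kmer, 1L, k - 1L)
    suff <- substr(km$kmer, 2L, k)
    all_pref <- unique(pref); all_suff <- unique(suff)
    first_node <- substr(utg$sequence, 1L, k - 1L)
    last_node <- substr(utg$sequence, nchar(utg$sequence) - k + 2L,
                        nchar(utg$sequence))
    dangling <- !(first_node %chin% all_suff) | !(last_node %chin% all_pref)
    is_tip <- dangling & nchar(utg$sequence) < 2L * k
    ## only clip when something else remains
    if (!any(is_tip) || all(is_tip)) return(km)
    tip_kmers <- unique(seq_kmers(utg$sequence[is_tip], k))
    km2 <- km[!kmer %chin% tip_kmers]
    if (nrow(km2) == nrow(km)) return(km)
    km <- km2
  }
  km
}

## unitigs with per-chain node bookkeeping kept minimal (used by clip/pop)
kmer_unitigs_raw <- function(km, k) kmer_unitigs(km, k)

## drop the lower-coverage branch of simple two-path bubbles
pop_bubbles <- function(km, k) {
  utg <- kmer_unitigs_raw(km, k)
  if (nrow(utg) < 2L) return(km)
  fn <- substr(utg$sequence, 1L, k - 1L)
  ln <- substr(utg$sequence, nchar(utg$sequence) - k + 2L, nchar(utg$sequence))
  key <- paste(fn, ln)
  dup <- key[duplicated(key)]
  if (!length(dup)) return(km)
  drop <- integer(0)
  for (d in unique(dup)) {
    grp <- which(key == d)
    if (diff(range(nchar(utg$sequence[grp]))) > k) next  # not a simple bubble
    ## a unitig and its own reverse complement are one object in the
    ## strand-symmetric graph, not a bubble
    if (length(unique(canonical_seq(utg$sequence[grp]))) < length(grp)) next
    keep <- grp[which.max(utg$mean_cov[grp])]
    drop <- c(drop, setdiff(grp, keep))
  }
  if (!length(drop)) return(km)
  bad <- unique(seq_kmers(utg$sequence[drop], k))
  keep_kmers <- unique(seq_kmers(utg$sequence[-drop], k))
  km[!kmer %chin% setdiff(bad, keep_kmers)]
}

#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length at least L together
#' contain at least half of the total assembly bases.
#'
#' @param lengths non-empty numeric vector of contig lengths.
#' @return the N50 in bp.
#' @export
#' @examples
#' n50(c(300, 200, 100))  # 300
n50 <- function(lengths) {
  if (!length(lengths)) stop("lengths must be non-empty", call. = FALSE)
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param contigs a `contig_set` from [assemble()].
#' @return data.frame with `n_contigs`, `mean_len`, `max_len`, `n50`.
#' @export
assembly_stats <- function(contigs) {
  if (!nrow(contigs))
    return(data.frame(n_contigs = 0L, mean_len = 0, max_len = 0, n50 = 0))
  data.frame(n_contigs = nrow(contigs),
             mean_len = mean(contigs$length),
             max_len = max(contigs$length),
             n50 = n50(contigs$length))
}

#' Sweep k-mer sizes and pick the best assembly
#'
#' Runs [assemble()] for each k and chooses the k maximising N50, with ties
#' broken by the longest contig and then by the smaller k.
#'
#' @param reads reads as for [assemble()].
#' @param k_values odd k-mer sizes to try.
#' @param ... passed to [assemble()].
#' @return list with `chosen_k`, `stats` (per-k table) and `contigs`
#'   (the assembly at the chosen k).
#' @export
k_sweep <- function(reads, k_values, ...) {
  if (!length(k_values)) stop("at least one k value required", call. = FALSE)
  asms <- lapply(k_values, function(k) assemble(reads, k, ...))
  st <- do.call(rbind, lapply(asms, assembly_stats))
  st <- cbind(data.frame(k = as.integer(k_values)), st)
  ord <- order(-st$n50, -st$max_len, st$k)
  best <- ord[1]
  list(chosen_k = st$k[best], stats = st, contigs = asms[[best]])
}

#' Write assembly statistics as a TSV report
#'
#' Row names follow the conventional shotgun-assembly summary (total number
#' of contigs, mean and longest contig length, N50).
#'
#' @param contigs a `contig_set`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_assembly_stats <- function(contigs, path) {
  st <- assembly_stats(contigs)
  out <- data.frame(
    statistic = c("Total number of contigs", "Mean contig length",
                  "Longest contig", "N50"),
    value = c(st$n_contigs, round(st$mean_len, 1), st$max_len, st$n50))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write contigs as FASTA (headers carry k and mean k-mer coverage)
#' @param contigs a `contig_set`.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_contigs <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- sprintf("%s k=%d cov=%.1f", contigs$id, contigs$k,
                      contigs$mean_kmer_coverage)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read contigs from a FASTA file (external-assembler drop-in)
#' @param path FASTA path.
#' @param k k value to record (0 if unknown).
#' @return a `contig_set`.
#' @export
read_contigs <- function(path, k = 0L) {
  x <- Biostrings::readDNAStringSet(path)
  out <- data.table(id = sub(" .*", "", names(x)),
                    sequence = as.character(x),
                    length = Biostrings::width(x),
                    k = as.integer(k),
                    mean_kmer_coverage = NA_real_)
  class(out) <- c("contig_set", class(out))
  out
}
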