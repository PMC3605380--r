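## Low-level DNA string helpers shared across modules. Sequences are plain
## character scalars/vectors internally; Biostrings objects only at the edges.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## uniform random DNA string of length n (uses current RNG state)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## all k-length substrings of each sequence, concatenated
seq_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), k:n)
  })
  unlist(out, use.names = FALSE)
}

## start positions and words of width w for a single sequence
seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(data.table(word = character(0), pos = integer(0)))
  data.table(word = substring(s, seq_len(n - w + 1L), w:(n)),
             pos = seq_len(n - w + 1L))
}

## number of mismatching characters between equal-length string pairs
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

## lexicographically smaller of a sequence and its reverse complement
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## substring on a circular sequence (1-based start, may wrap past the end)
circular_substr <- function(s, start, len) {
  n <- nchar(s)
  stopifnot(len <= 2L * n)
  start <- ((start - 1L) %% n) + 1L
  end <- start + len - 1L
  if (end <= n) substr(s, start, end)
  else paste0(substr(s, start, n), substr(s, 1L, end - n))
}

## simple argument guards -----------------------------------------------------

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
}

check_dna <- function(x, name = deparse(substitute(x))) {
  if (!is.character(x) || any(is.na(x)))
    stop(sprintf("`%s` must be a character vector of DNA", name), call. = FALSE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("`%s` contains characters outside A/C/G/T", name),
         call. = FALSE)
  invisible(x)
}
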