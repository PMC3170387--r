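# Low-level sequence and algorithm helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement via Biostrings. Accepts plain character
#' vectors and returns plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. A/C/G/T string drawn from the current RNG state.
#'
#' @param n sequence length in nucleotides.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Mismatch counts between equal-length string pairs (vectorised Hamming
# distance). Strings of unequal length within a pair are an error.
hamming_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  la <- nchar(a)
  if (any(la != nchar(b))) stop("hamming_mismatches: unequal string lengths")
  out <- integer(length(a))
  for (len in unique(la)) {
    idx <- which(la == len)
    if (len == 0L) next
    A <- matrix(unlist(strsplit(a[idx], "", fixed = TRUE), use.names = FALSE),
                nrow = len)
    B <- matrix(unlist(strsplit(b[idx], "", fixed = TRUE), use.names = FALSE),
                nrow = len)
    out[idx] <- colSums(A != B)
  }
  out
}

# Longest strictly increasing subsequence; returns indices into x.
# O(n log n) patience algorithm; x must be numeric without NA.
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  tail_val <- numeric(0)   # smallest tail value of an LIS of each length
  tail_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 0.5, tail_val)  # tails strictly below x[i]
    prev[i] <- if (pos > 0L) tail_idx[pos] else 0L
    tail_val[pos + 1L] <- x[i]
    tail_idx[pos + 1L] <- i
  }
  out <- integer(length(tail_idx))
  k <- tail_idx[length(tail_idx)]
  for (j in rev(seq_along(out))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

# Phred+33 encoding helpers. QV integers <-> ASCII strings.
qv_to_string <- function(qv) {
  vapply(qv, function(v) intToUtf8(pmin(pmax(v, 0L), 93L) + 33L), "")
}

string_to_qv <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

# Mean QV per quality string, computed efficiently for uniform lengths.
mean_qv <- function(s) {
  if (!length(s)) return(numeric(0))
  lens <- nchar(s)
  out <- numeric(length(s))
  for (len in unique(lens)) {
    idx <- which(lens == len)
    if (len == 0L) { out[idx] <- NaN; next }
    m <- matrix(utf8ToInt(paste(s[idx], collapse = "")) - 33L, nrow = len)
    out[idx] <- colMeans(m)
  }
  out
}

# k-mer position table for a reference string: data.table(kmer, pos),
# 1-based positions; k-mers containing non-ACGT characters are dropped.
kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(data.table::data.table(kmer = character(0), pos = integer(0)))
  }
  pos <- seq_len(n - k + 1L)
  km <- substring(seq, pos, pos + k - 1L)
  keep <- !grepl("[^ACGT]", km)
  data.table::data.table(kmer = km[keep], pos = pos[keep], key = "kmer")
}

# All k-mers of a set of equal-length reads as one character vector.
read_kmers <- function(reads, k) {
  lens <- nchar(reads)
  out <- vector("list", length(unique(lens)))
  i <- 1L
  for (len in unique(lens)) {
    if (len < k) next
    rr <- reads[lens == len]
    offs <- seq_len(len - k + 1L)
    out[[i]] <- unlist(lapply(offs, function(o) substring(rr, o, o + k - 1L)),
                       use.names = FALSE)
    i <- i + 1L
  }
  unlist(out, use.names = FALSE)
}

# Canonical form (lexicographic min of k-mer and its reverse complement).
canonical_kmers <- function(km) {
  if (!length(km)) return(character(0))
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}
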