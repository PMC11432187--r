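# Integer encoding of DNA k-mers.
#
# A k-mer over {A,C,G,T} is encoded as a base-4 integer with A=0, C=1, G=2,
# T=3 and the first base in the most significant digit, so "AA...A" -> 0 and
# "TT...T" -> 4^k - 1.  For k = 10 the code space (4^10 = 1,048,576) fits
# comfortably in a dense vector, which makes counting (tabulate) and lookup
# (direct indexing) O(1) per window.  Codes are stored as doubles internally
# because intermediate products exceed .Machine$integer.max for k > 15, but
# all values used here are exact integers below 2^31.

#' Convert DNA strings to integer base codes
#'
#' Maps `A`, `C`, `G`, `T` (case-insensitive) to 0:3; any other character
#' (e.g. `N`) becomes `NA`.
#'
#' @param x Character vector of DNA strings.
#' @return Integer vector of concatenated per-base codes, with an attribute
#'   `lengths` giving the length of each input string.
#' @keywords internal
dna_to_base_codes <- function(x) {
  raw <- charToRaw(paste(x, collapse = ""))
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("ACGTacgt")) + 1L] <- rep(0:3, 2L)
  codes <- lut[as.integer(raw) + 1L]
  attr(codes, "lengths") <- nchar(x)
  codes
}

#' Encode all k-length windows of a base-code vector
#'
#' @param b Integer vector of per-base codes (0:3 or NA).
#' @param k Window width.
#' @return Numeric vector of window codes, length `length(b) - k + 1`;
#'   windows containing an invalid base are `NA`.
#' @keywords internal
window_codes <- function(b, k) {
  n <- length(b)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in seq_len(k)) {
    out <- out + as.numeric(b[j:(m + j - 1L)]) * 4^(k - j)
  }
  out
}

#' Encode reverse-complement k-length windows
#'
#' Returns, for every forward window, the code of its reverse complement
#' (complement is 3 - base; order reversed).
#' @inheritParams window_codes
#' @keywords internal
window_codes_rc <- function(b, k) {
  n <- length(b)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in seq_len(k)) {
    out <- out + (3 - as.numeric(b[j:(m + j - 1L)])) * 4^(j - 1L)
  }
  out
}

#' Convert k-mer strings to codes
#'
#' @param kmers Character vector of equal-length DNA words.
#' @return Numeric codes (NA for words with invalid characters).
#' @export
#' @examples
#' kmer_to_code(c("AAA", "ACG", "TTT"))
kmer_to_code <- function(kmers) {
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  b <- dna_to_base_codes(kmers)
  mat <- matrix(b, nrow = k)
  drop(crossprod(mat, 4^((k - 1):0)))
}

#' Convert integer codes back to k-mer strings
#'
#' @param codes Numeric vector of codes in `[0, 4^k)`.
#' @param k Word length.
#' @return Character vector of DNA words.
#' @export
code_to_kmer <- function(codes, k) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(codes))
  digits <- matrix("", nrow = length(codes), ncol = k)
  rem <- codes
  for (j in seq_len(k)) {
    d <- rem %/% 4^(k - j)
    rem <- rem - d * 4^(k - j)
    digits[, j] <- bases[d + 1L]
  }
  apply(digits, 1L, paste, collapse = "")
}

#' Reverse-complement a k-mer code
#'
#' @inheritParams code_to_kmer
#' @return Codes of the reverse-complement words.
#' @export
revcomp_code <- function(codes, k) {
  out <- numeric(length(codes))
  rem <- codes
  for (j in seq_len(k)) {
    d <- rem %/% 4^(k - j)
    rem <- rem - d * 4^(k - j)
    out <- out + (3 - d) * 4^(j - 1L)
  }
  out
}

#' Reverse-complement DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()].
#' @param x Character vector of DNA strings.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Score every code in [0, 4^k) against a per-position score table.
# `score_tab` is a 4 x k matrix (rows A,C,G,T); returns the sum of the
# position scores for each word, as a dense vector indexed by code + 1.
all_code_scores <- function(score_tab) {
  k <- ncol(score_tab)
  n <- 4^k
  codes <- seq_len(n) - 1
  out <- numeric(n)
  rem <- codes
  for (j in seq_len(k)) {
    d <- rem %/% 4^(k - j)
    rem <- rem - d * 4^(k - j)
    out <- out + score_tab[cbind(d + 1, j)]
  }
  out
}
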