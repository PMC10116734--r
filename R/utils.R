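#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Bases and qualities -----------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character vectors of DNA
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred+33 encode / decode
#' @noRd
phred_to_chr <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' @noRd
chr_to_phred <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}

#' Split strings into single-character matrices/vectors cheaply
#' @noRd
str_bytes <- function(s) charToRaw(s)

#' Round half away from zero (base round() is banker's rounding)
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Lower median: for even n, the smaller of the two middle values
#' @noRd
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  as.numeric(x[ceiling(n / 2)])
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Derive a stream-specific 32-bit seed from a base seed
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + stream * 1013L) %% 2147483647L
}
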