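#' @importFrom stats cor pchisq phyper rbinom rnbinom rnorm runif p.adjust
#'   fisher.test setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input. Only the DNA alphabet A/C/G/T is handled;
#' sequences are expected to have been normalised (U to T, upper case) by
#' the readers in this package.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Integer encoding A=1, C=2, G=3, T=4; NA for anything else.
encode_dna <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
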