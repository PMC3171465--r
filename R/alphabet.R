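#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the PAML rate-matrix convention
#' (A R N D C Q E G H I L K M F P S T W Y V). Every frequency vector and
#' every rate/transition matrix in this package is indexed in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# index lookup, gap and unknown characters
.aa_index <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)
.gap_char <- "-"
.unknown_char <- "X"

#' Map amino-acid letters to alphabet indices
#'
#' @param x character vector of single letters.
#' @return Integer indices into [AA_ALPHABET]; `NA` for gap/unknown.
#' @keywords internal
aa_index <- function(x) {
  unname(.aa_index[x])
}

# validate a length-20 probability vector
.check_distribution <- function(p, arg = "p", tol = 1e-6) {
  if (!is.numeric(p) || length(p) != length(AA_ALPHABET)) {
    stop(sprintf("'%s' must be a numeric vector of length %d", arg,
                 length(AA_ALPHABET)), call. = FALSE)
  }
  if (any(p < -1e-12)) {
    stop(sprintf("'%s' has negative entries", arg), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' does not sum to 1 (sum = %.8f)", arg, sum(p)),
         call. = FALSE)
  }
  invisible(TRUE)
}

# x*log(x) with the 0*log(0) = 0 convention
.xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# x*log(x/y) with 0*log(0/y) = 0; caller guarantees y > 0 wherever x > 0
.xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / y[pos])
  out
}
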