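# internal helpers

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Display rounding used by the summary tables. `base::round()` rounds half
#' to even; array summary tables round half up, so 0.75 at 1 dp is 0.8.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# population standard deviation (denominator n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

ACGT <- c("A", "C", "G", "T")

is_acgt <- function(x) x %in% ACGT

`%||%` <- function(a, b) if (is.null(a)) b else a
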