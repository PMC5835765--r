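#' Round half away from zero
#'
#' Fixed-point rounding in which exact halves go up (e.g. 23.45 -> 23.5),
#' matching the convention used when percentages are reported to one
#' decimal in clinical tables. `base::round()` rounds halves to even and
#' would print 23.4 for the same value.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(23.45, 51.2195, 60.9756) , 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# percentage of a count over a total, printed to one decimal
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fcd <- function(msg, class) {
  rlang::abort(msg, class = paste0("fcdsre_", class))
}
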