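#' Round half away from zero
#'
#' Decimal rounding with ties broken away from zero, the convention used for
#' printed fold changes and percentages in the reporting layer (base
#' [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25), 1)   # 0.3, -0.3
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # add a half-ulp nudge so values like 4.45 stored as 4.4499999... still
  # round up; magnitudes here are table-scale so this is safe
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a count as "k/n (pct%)"
#'
#' Reporting rule for summary lines: percentage is 100*k/n rounded half away
#' from zero to one decimal.
#'
#' @param k count of interest.
#' @param n total.
#' @return character scalar, e.g. `"67/559 (12.0%)"`.
#' @export
format_fraction <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  sprintf("%d/%d (%.1f%%)", k, n, round_half_away(100 * k / n, 1))
}

# internal: quiet-able progress messages
mir_msg <- function(...) {
  if (isTRUE(getOption("myelomiR.verbose", TRUE))) message(...)
  invisible(NULL)
}

# internal: derive a reproducible sub-seed (< 2^31) from a master seed and a
# stream name, so each pipeline stage draws from its own stream
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
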