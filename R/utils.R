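#' Positive part of an age offset
#'
#' Truncated-age basis used by the piecewise-linear trajectory model:
#' `(age - knot)^+`, equal to `age - knot` when positive and 0 otherwise.
#' The slope coefficient on this term is the *change* in slope at `knot`.
#'
#' @param age Numeric vector of ages in years.
#' @param knot Knot location in years.
#' @return Numeric vector, same length as `age`.
#' @examples
#' age_knot(c(5, 9), 6) # 0, 3
#' @export
age_knot <- function(age, knot) pmax(age - knot, 0)

#' Convert an annual methylation change to a total change over a period
#'
#' A per-year slope on the beta-value scale (proportion methylated per year)
#' is converted to the implied total change in percentage points over
#' `years` of follow-up: `100 * b * years`. The sign is retained, so a
#' negative slope yields a negative (decreasing) total change.
#'
#' @param b Annual change in beta value (per year).
#' @param years Length of the period in years (default 18, birth to late
#'   adolescence).
#' @return Total change in percentage points of methylation.
#' @examples
#' annual_to_total_change(-9.24e-4) # about -1.66 over 18 years
#' @export
annual_to_total_change <- function(b, years = 18) 100 * b * years

# z-score standardization used for continuous covariates; constant columns
# are returned as zeros rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
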