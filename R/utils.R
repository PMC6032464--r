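#' @keywords internal
"_PACKAGE"

## classed conditions so callers/tests can distinguish bad files from bad data
dce_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dce_error")))
}

dce_format_error <- function(msg) dce_stop(msg, "dce_format_error")
dce_validation_error <- function(msg) dce_stop(msg, "dce_validation_error")
dce_conversion_error <- function(msg) dce_stop(msg, "dce_conversion_error")
dce_domain_error <- function(msg) dce_stop(msg, "dce_domain_error")

#' Standard deviation with selectable convention
#'
#' Descriptive statistics in this package default to the population
#' (divide-by-n) convention; the sample (divide-by-n-1) convention is available
#' everywhere a summary is produced.
#'
#' @param x numeric vector.
#' @param type `"population"` (divide by n, default) or `"sample"`.
#' @return The standard deviation as a single number.
#' @export
sd_conv <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (type == "sample") {
    if (n < 2L) return(0)
    return(stats::sd(x))
  }
  sqrt(sum((x - mean(x))^2) / n)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up), used when formatting percentages so
#' that e.g. 87.5 prints as 88.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # snap values a hair below an exact half (binary representation error of
  # products like 0.875 * 0.7) back onto it before applying the rule
  z <- round(abs(x) * f, 9)
  sign(x) * floor(z + 0.5) / f
}

## truncated-normal quantile via inverse-CDF; vectorised over p
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + p * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with the
#' given location/scale truncated to `[lower, upper]`. Used to state what the
#' synthetic-cohort generator actually produces: truncation at physical bounds
#' shifts the moments away from the nominal location/scale.
#'
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds.
#' @return A list with elements `mean` and `sd` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a)
  pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mean + sd * (pa - pb) / Z
  v <- sd^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

## cumulative trapezoidal integral, same length as x (first element 0)
cumtrapz1 <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}
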