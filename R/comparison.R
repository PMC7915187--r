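# Validation against an external reference series.  The simulated
# percent-of-baseline series and the reference (percent of previous year)
# are observed at different dates, so the estimates are linearly
# interpolated to the reference dates before computing the product-moment
# correlation.

#' Piecewise-linear interpolation at query dates
#'
#' Interpolates in calendar-day units.  Extrapolation is refused: every
#' query date must lie within the observed range.
#'
#' @param dates `Date` (or numeric) knots, strictly increasing.
#' @param values values at the knots.
#' @param query_dates dates at which to interpolate.
#' @return numeric vector of interpolated values.
#' @export
interpolate_to_dates <- function(dates, values, query_dates) {
  x <- as.numeric(as.Date(dates))
  xq <- as.numeric(as.Date(query_dates))
  stopifnot(length(x) == length(values), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("knot dates must be strictly increasing")
  if (any(xq < min(x)) || any(xq > max(x))) {
    stop("query date outside the observed range (no extrapolation)")
  }
  stats::approx(x, values, xout = xq, method = "linear")$y
}

#' Correlate a volume estimate series with a reference series
#'
#' Reference dates falling inside the estimate date range are kept (the
#' count of dropped points is reported); the estimates'
#' percent-of-baseline values are interpolated to those dates, and the
#' product-moment correlation r is computed, with a two-sided p-value from
#' `t = r sqrt((n-2) / (1-r^2))` on n-2 degrees of freedom (the p-value
#' method is a package choice; it is labelled in the output).
#'
#' @param estimates a `volume_estimate_series`.
#' @param reference a [reference_series()].
#' @param invert if `TRUE`, interpolate the reference to the estimate dates
#'   instead of the default direction.
#' @return a `comparison_result`: list with `r`, `n`, `p_value`, `p_method`,
#'   `n_dropped`, `aligned` (data.frame of date, f_est, f_ref).
#' @export
compare_series <- function(estimates, reference, invert = FALSE) {
  stopifnot(inherits(estimates, "volume_estimate_series"),
            inherits(reference, "reference_series"))
  if (!invert) {
    keep <- reference$date >= min(estimates$date) &
      reference$date <= max(estimates$date)
    n_dropped <- sum(!keep)
    dates <- reference$date[keep]
    f_ref <- reference$percent[keep]
    if (length(dates) < 3) stop("fewer than 3 reference points overlap")
    f_est <- interpolate_to_dates(estimates$date,
                                  estimates$percent_of_baseline, dates)
  } else {
    keep <- estimates$date >= min(reference$date) &
      estimates$date <= max(reference$date)
    n_dropped <- sum(!keep)
    dates <- estimates$date[keep]
    f_est <- estimates$percent_of_baseline[keep]
    if (length(dates) < 3) stop("fewer than 3 estimate points overlap")
    f_ref <- interpolate_to_dates(reference$date, reference$percent, dates)
  }

  n <- length(dates)
  da <- f_est - mean(f_est)
  db <- f_ref - mean(f_ref)
  denom <- sqrt(sum(da^2) * sum(db^2))
  if (denom == 0) stop("zero variance in an aligned series")
  r <- sum(da * db) / denom
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  structure(list(r = r, n = n, p_value = p,
                 p_method = "t approximation, n-2 df",
                 n_dropped = n_dropped,
                 aligned = data.frame(date = dates, f_est = f_est,
                                      f_ref = f_ref)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: r = %.3f (n = %d, p = %.2g, %s)\n",
              x$r, x$n, x$p_value, x$p_method))
  if (x$n_dropped > 0) {
    cat(sprintf("  %d reference point(s) outside the estimate range dropped\n",
                x$n_dropped))
  }
  invisible(x)
}
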