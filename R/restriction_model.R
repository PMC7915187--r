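# Per-state restriction-rate model.  Each restriction state i carries a
# gamma distribution Gamma(alpha_i, beta_i) for the multiplicative factor x
# applied to a hospital's reference weekly volume.  Parameters are pinned
# down by a (median, variance) pair: the variance fixes alpha = v * beta^2,
# leaving a one-dimensional root-find on beta for the median.  The gamma
# support is unbounded above, so an unrestricted hospital can slightly
# exceed its reference week (x > 1 is allowed by design).

#' Solve gamma shape/rate from a (median, variance) specification
#'
#' Finds `(alpha, beta)` with `alpha / beta^2 = variance` exactly and
#' `qgamma(0.5, alpha, beta) = median` to within 1e-9, by bracketed
#' root-finding on `beta`.  Since the mean is `variance * beta` and the
#' median sits just below the mean, `median / variance` is an excellent
#' starting bracket centre for all practical inputs.
#'
#' @param median target median of the distribution, > 0.
#' @param variance target variance, > 0.
#' @return list with `shape`, `rate`, `mean`, `median`, `variance`.
#' @export
solve_gamma_params <- function(median, variance) {
  if (!is.numeric(median) || median <= 0) stop("median must be > 0")
  if (!is.numeric(variance) || variance <= 0) stop("variance must be > 0")

  f <- function(beta) {
    stats::qgamma(0.5, shape = variance * beta^2, rate = beta) - median
  }
  lo <- median / variance
  hi <- lo
  for (i in 1:200) {
    if (f(lo) < 0) break
    lo <- lo / 2
  }
  for (i in 1:200) {
    if (f(hi) > 0) break
    hi <- hi * 2
  }
  if (!(f(lo) < 0 && f(hi) > 0)) stop("failed to bracket gamma rate")
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps * lo)
  beta <- root$root
  alpha <- variance * beta^2
  med <- stats::qgamma(0.5, shape = alpha, rate = beta)
  if (abs(med - median) > 1e-9) stop("gamma median root-find did not converge")
  list(shape = alpha, rate = beta, mean = alpha / beta,
       median = med, variance = alpha / beta^2)
}

# Named scenario levels for states 1-4 (no restriction .. no scheduled
# surgery), interpreted as medians of the per-state gamma distributions.
SCENARIO_MEDIANS <- list(
  baseline    = c(1.0, 0.7, 0.4, 0.10),
  optimistic  = c(1.0, 0.8, 0.5, 0.25),
  pessimistic = c(1.0, 0.5, 0.3, 0.03)
)

#' Assemble a restriction scenario
#'
#' A scenario fixes one gamma restriction-rate distribution per state.  The
#' built-in scenarios share state 1 at level 1.0 (unrestricted) and a common
#' variance of 0.005; their levels for states 2-4 encode progressively
#' stronger restriction.  Levels are treated as medians; set
#' `interpret = "mean"` to treat them as means instead (then
#' `alpha/beta = level` exactly).
#'
#' @param name `"baseline"`, `"optimistic"`, `"pessimistic"`, or any name
#'   when `medians` is supplied.
#' @param variance shared variance of the four gamma distributions.
#' @param medians optional custom length-4 vector of levels, strictly
#'   decreasing over states 1-4.
#' @param interpret `"median"` (default) or `"mean"`: how the level values
#'   parameterize the gamma distributions.
#' @return a `restriction_scenario`: list with `name`, `levels`, `variance`,
#'   `params` (length-4 list from [solve_gamma_params()]), `means`.
#' @export
build_scenario <- function(name, variance = 0.005, medians = NULL,
                           interpret = c("median", "mean")) {
  interpret <- match.arg(interpret)
  if (is.null(medians)) {
    if (!name %in% names(SCENARIO_MEDIANS)) {
      stop("unknown scenario '", name, "'; supply custom medians")
    }
    medians <- SCENARIO_MEDIANS[[name]]
  }
  stopifnot(length(medians) == N_STATES, all(medians > 0))
  if (any(diff(medians) >= 0)) {
    stop("scenario levels must strictly decrease over states 1-4")
  }
  if (variance <= 0) stop("variance must be > 0")
  params <- lapply(medians, function(m) {
    if (interpret == "median") {
      solve_gamma_params(m, variance)
    } else {
      beta <- m / variance
      alpha <- variance * beta^2
      list(shape = alpha, rate = beta, mean = m,
           median = stats::qgamma(0.5, alpha, rate = beta),
           variance = variance)
    }
  })
  structure(list(name = name, levels = medians, variance = variance,
                 interpret = interpret, params = params,
                 means = vapply(params, `[[`, numeric(1), "mean")),
            class = "restriction_scenario")
}

#' @export
print.restriction_scenario <- function(x, ...) {
  cat(sprintf("restriction_scenario '%s' (%ss %s, variance %g)\n",
              x$name, x$interpret,
              paste(format(x$levels), collapse = ", "), x$variance))
  invisible(x)
}
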