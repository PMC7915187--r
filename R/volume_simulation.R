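# Monte Carlo propagation of restriction states through the hospital
# registry.  Each iteration allocates every hospital a starting state from
# the first poll's distribution (independent of hospital size), evolves it
# hospital-by-hospital through the estimated weekly transition matrices, and
# draws an independent gamma restriction rate per hospital-week; weekly
# national totals are the size-weighted sums.  Percentile summaries over
# iterations give the 95% intervals.

#' Draw initial restriction states for all hospitals
#'
#' Each hospital's state is drawn independently and categorically from the
#' first-week distribution, independent of hospital size.
#'
#' @param registry a [hospital_registry()].
#' @param y1 length-4 probability vector (first poll's distribution).
#' @return integer vector of states in 1..4, one per hospital.
#' @export
allocate_initial <- function(registry, y1) {
  stopifnot(length(y1) == N_STATES, abs(sum(y1) - 1) < 1e-6, all(y1 >= 0))
  n <- nrow(registry)
  if (n == 0) return(integer(0))
  sample.int(N_STATES, n, replace = TRUE, prob = y1)
}

# One evolution step for a vector (or matrix) of states under matrix P.
# Grouping by current state keeps this fully vectorized: four sample.int
# calls regardless of the number of hospitals.
evolve_step <- function(states, P) {
  out <- states
  for (i in seq_len(N_STATES)) {
    idx <- which(states == i)
    if (length(idx) > 0) {
      out[idx] <- sample.int(N_STATES, length(idx), replace = TRUE,
                             prob = P[i, ])
    }
  }
  out
}

#' Evolve per-hospital states through a transition chain
#'
#' @param states integer vector of initial states (week 1), one per hospital.
#' @param chain a `transition_chain` (or plain list of 4x4 matrices); matrix
#'   t maps week t to week t+1.
#' @return integer matrix, hospitals x weeks (weeks = chain length + 1),
#'   column 1 being the initial states.
#' @export
evolve_states <- function(states, chain) {
  mats <- if (inherits(chain, "transition_chain")) chain$matrices else chain
  n_weeks <- length(mats) + 1L
  out <- matrix(NA_integer_, length(states), n_weeks)
  out[, 1] <- states
  for (t in seq_len(length(mats))) {
    out[, t + 1L] <- evolve_step(out[, t], mats[[t]])
  }
  out
}

#' Monte Carlo simulation of weekly general-anesthesia totals
#'
#' @param registry a [hospital_registry()].
#' @param chain a `transition_chain` aligned with the poll dates (length
#'   T-1 for T weeks).
#' @param y1 first-week state distribution used for allocation.
#' @param scenario a [build_scenario()] result.
#' @param iterations Monte Carlo iterations (default 1000).
#' @param seed integer seed; identical inputs and seed reproduce the run
#'   bit-for-bit.
#' @param dates optional vector of poll dates for the simulated weeks;
#'   defaults to the chain's dates when it carries them.
#' @param reallocate if `TRUE` (default) hospitals are re-allocated to
#'   initial states in every iteration, propagating allocation uncertainty;
#'   if `FALSE` one allocation is drawn and shared by all iterations.
#' @param keep_states if `TRUE`, retain the full states array
#'   (hospitals x weeks x iterations); off by default to bound memory.
#' @return a `simulation_run`: list with `weekly_totals` (weeks x
#'   iterations, cases/week), `dates`, `iterations`, `seed`, `scenario`,
#'   `baseline_total` (sum of weekly references), optionally `states`.
#' @export
simulate_weekly_volumes <- function(registry, chain, y1, scenario,
                                    iterations = 1000L, seed = 1L,
                                    dates = NULL,
                                    reallocate = TRUE, keep_states = FALSE) {
  stopifnot(inherits(scenario, "restriction_scenario"), iterations >= 1)
  mats <- if (inherits(chain, "transition_chain")) chain$matrices else chain
  if (is.null(dates) && inherits(chain, "transition_chain")) {
    dates <- chain$dates
  }
  n_weeks <- length(mats) + 1L
  if (!is.null(dates) && length(dates) != n_weeks) {
    stop("chain is misaligned with its poll dates")
  }
  H <- nrow(registry)
  w <- registry$weekly_reference
  alpha <- vapply(scenario$params, `[[`, numeric(1), "shape")
  beta <- vapply(scenario$params, `[[`, numeric(1), "rate")

  set.seed(as.integer(seed))
  totals <- matrix(0, n_weeks, iterations)
  states_keep <- if (keep_states) {
    array(NA_integer_, c(H, n_weeks, iterations))
  } else NULL

  if (H > 0) {
    S <- if (reallocate) {
      matrix(sample.int(N_STATES, H * iterations, replace = TRUE, prob = y1),
             H, iterations)
    } else {
      matrix(rep(allocate_initial(registry, y1), iterations), H, iterations)
    }
    for (t in seq_len(n_weeks)) {
      x <- stats::rgamma(H * iterations, shape = alpha[S], rate = beta[S])
      totals[t, ] <- colSums(w * matrix(x, H, iterations))
      if (keep_states) states_keep[, t, ] <- S
      if (t < n_weeks) S <- evolve_step(S, mats[[t]])
    }
  }

  structure(list(weekly_totals = totals, dates = dates,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 scenario = scenario$name, baseline_total = sum(w),
                 states = states_keep),
            class = "simulation_run")
}

#' Summarize a simulation run into a weekly estimate series
#'
#' Per week: the median and the 2.5th / 97.5th percentiles of the simulated
#' totals across iterations (percentiles by linear interpolation between
#' order statistics, `quantile type 7`), and the median as a percent of the
#' registry's summed weekly reference.
#'
#' @param run a [simulate_weekly_volumes()] result.
#' @param registry the [hospital_registry()] used in the run (supplies the
#'   baseline weekly total).
#' @return a `volume_estimate_series` data.frame: `date`, `median`,
#'   `ci_low`, `ci_high`, `percent_of_baseline`.
#' @export
summarize_volumes <- function(run, registry) {
  stopifnot(inherits(run, "simulation_run"))
  tot <- run$weekly_totals
  if (length(tot) == 0) stop("empty simulation run")
  baseline <- sum(registry$weekly_reference)
  med <- apply(tot, 1, stats::median)
  lo <- apply(tot, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(tot, 1, stats::quantile, probs = 0.975, names = FALSE)
  dates <- if (is.null(run$dates)) seq_len(nrow(tot)) else run$dates
  out <- data.frame(date = dates, median = med, ci_low = lo, ci_high = hi,
                    percent_of_baseline = med / baseline * 100)
  attr(out, "baseline_total") <- baseline
  attr(out, "seed") <- run$seed
  attr(out, "scenario") <- run$scenario
  class(out) <- c("volume_estimate_series", "data.frame")
  out
}
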