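# Seeded generator of synthetic inputs with the statistical structure the
# analysis assumes: multinomial poll counts over a latent banded Markov
# chain started from "no restrictions", weekly sample sizes in the
# tens-to-hundreds, and a right-skewed registry of ~1989 hospitals whose
# weekly baseline sums to ~4.45e4 cases.  Latent truth is always retained
# so recovery experiments can measure estimation error.

#' Configuration of the synthetic world
#'
#' Defaults mirror the observed survey campaign: 17 weekly polls with 47 to
#' 288 responses, 1989 eligible hospitals, and a pre-disruption national
#' volume of 44,500 general-anesthesia cases per week.
#'
#' @param n_weeks number of poll dates (>= 2).
#' @param n_hospitals registry size (>= 1).
#' @param weekly_baseline_total summed weekly reference volume, cases/week.
#' @param sample_size_range inclusive integer range of weekly poll sizes.
#' @param volatility non-negative scale of week-to-week transition
#'   perturbations away from the identity; 0 freezes all movement.
#' @param top_decile_share share of total volume carried by the largest 10%
#'   of hospitals (shapes the log-normal size distribution).
#' @param start_date date of the first poll.
#' @param seed master seed; all generator randomness flows from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_weeks = 17L, n_hospitals = 1989L,
                             weekly_baseline_total = 44500,
                             sample_size_range = c(47L, 288L),
                             volatility = 0.3, top_decile_share = 0.4,
                             start_date = as.Date("2020-03-13"),
                             seed = 1L) {
  stopifnot(n_weeks >= 2, n_hospitals >= 1, volatility >= 0,
            length(sample_size_range) == 2, all(sample_size_range >= 1),
            sample_size_range[1] <= sample_size_range[2],
            weekly_baseline_total > 0,
            top_decile_share > 0.1, top_decile_share < 1)
  structure(list(n_weeks = as.integer(n_weeks),
                 n_hospitals = as.integer(n_hospitals),
                 weekly_baseline_total = weekly_baseline_total,
                 sample_size_range = as.integer(sample_size_range),
                 volatility = volatility,
                 top_decile_share = top_decile_share,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random banded transition chain
#'
#' Each weekly matrix is the identity plus exponential perturbations on the
#' allowed off-diagonal band, row-normalized to the simplex; `volatility`
#' scales the perturbation, with 0 giving the identity exactly.
#'
#' @param config a [synthetic_config()].
#' @return list of `n_weeks - 1` [transition_matrix()] objects.
#' @export
make_transition_chain <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seeds(config$seed, 4)[1])
  lapply(seq_len(config$n_weeks - 1L), function(t) {
    P <- diag(N_STATES)
    for (k in seq_len(N_FREE)) {
      i <- FREE_ROW[k]; j <- FREE_COL[k]
      if (i != j) P[i, j] <- config$volatility * stats::rexp(1)
    }
    transition_matrix(P / rowSums(P), tol = 1e-12)
  })
}

#' Simulate an observed poll series from a latent chain
#'
#' The latent state distribution is propagated forward from the baseline
#' `(1, 0, 0, 0)`: the first poll reflects one step of movement
#' (`latent_1 = baseline %*% M_1`) and `latent_{t+1} = latent_t %*% M_t`
#' thereafter, so matrix 1 governs both the entry step and week 1 to 2 --
#' the same local-constancy convention the estimator's stacked windows
#' assume.  Each week's observed counts are a multinomial draw with a
#' sample size uniform on `sample_size_range`.  The latent truth
#' (distributions, chain, sample sizes) is attached as an attribute for
#' recovery experiments.
#'
#' @param chain list of `n_weeks - 1` transition matrices.
#' @param config a [synthetic_config()].
#' @return a [poll_series()] with attribute `truth` (list: `latent` matrix
#'   `n_weeks x 4`, `chain`, `sample_sizes`).
#' @export
simulate_polls <- function(chain, config) {
  stopifnot(inherits(config, "synthetic_config"),
            length(chain) == config$n_weeks - 1L)
  set.seed(derive_seeds(config$seed, 4)[2])
  baseline <- c(1, 0, 0, 0)
  W <- config$n_weeks
  latent <- matrix(NA_real_, W, N_STATES)
  latent[1, ] <- drop(baseline %*% chain[[1]])
  for (t in seq_len(W - 1L)) {
    latent[t + 1L, ] <- drop(latent[t, ] %*% chain[[t]])
  }
  sizes <- sample(config$sample_size_range[1]:config$sample_size_range[2],
                  W, replace = TRUE)
  counts <- t(vapply(seq_len(W), function(t) {
    drop(stats::rmultinom(1, sizes[t], latent[t, ]))
  }, numeric(N_STATES)))
  dates <- config$start_date + 7 * (seq_len(W) - 1L)
  out <- poll_series(dates, counts = counts, baseline = baseline)
  attr(out, "truth") <- list(latent = latent, chain = chain,
                             sample_sizes = sizes)
  out
}

#' Generate a right-skewed synthetic hospital registry
#'
#' Annual caseloads are log-normal with the shape chosen so the top decile
#' of hospitals carries `top_decile_share` of total volume, truncated below
#' at 100 annual cases (the eligibility floor), then affinely rescaled above
#' that floor so the summed weekly reference equals
#' `weekly_baseline_total` exactly.
#'
#' @param config a [synthetic_config()].
#' @return a [hospital_registry()].
#' @export
make_registry <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seeds(config$seed, 4)[3])
  n <- config$n_hospitals
  target_annual <- config$weekly_baseline_total * 52
  floor_annual <- 100
  if (target_annual <= floor_annual * n) {
    stop("weekly_baseline_total too small for n_hospitals at the 100-case floor")
  }
  # top-decile share s of a log-normal: s = 1 - Phi(qnorm(0.9) - sdlog)
  sdlog <- stats::qnorm(0.9) - stats::qnorm(1 - config$top_decile_share)
  meanlog <- log(target_annual / n) - sdlog^2 / 2
  annual <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:100) {
    small <- annual < floor_annual
    if (!any(small)) break
    annual[small] <- stats::rlnorm(sum(small), meanlog, sdlog)
  }
  annual[annual < floor_annual] <- floor_annual
  # rescale the excess over the floor: keeps min >= 100 and hits the total
  excess <- annual - floor_annual
  scale <- (target_annual - floor_annual * n) / sum(excess)
  annual <- floor_annual + excess * scale
  hospital_registry(sprintf("H%05d", seq_len(n)), annual)
}

#' Generate a noisy external reference series from an estimate series
#'
#' Emulates an independently observed percent series: the estimates'
#' percent-of-baseline values are read off at date-shifted query points
#' (clamped to the observed range) and perturbed with additive Gaussian
#' noise.
#'
#' @param estimates a `volume_estimate_series`.
#' @param noise_sd standard deviation of the additive noise, percent units.
#' @param seed integer seed.
#' @param shift_days calendar-day shift applied to the estimate dates.
#' @return a [reference_series()].
#' @export
make_reference_series <- function(estimates, noise_sd = 3, seed = 1L,
                                  shift_days = 3L) {
  stopifnot(nrow(estimates) >= 2, noise_sd >= 0)
  set.seed(as.integer(seed))
  q <- pmin(pmax(estimates$date + shift_days, min(estimates$date)),
            max(estimates$date))
  q <- unique(q)
  vals <- interpolate_to_dates(estimates$date, estimates$percent_of_baseline, q)
  vals <- pmax(vals + stats::rnorm(length(q), 0, noise_sd), 0)
  reference_series(q, vals)
}

#' Analytic expected volume series under the latent truth
#'
#' For a synthetic poll series, the expected weekly total is
#' `baseline_total * sum_i latent[t, i] * mu_i`, with `mu_i` the mean of the
#' scenario's state-i gamma distribution (allocation is size-independent,
#' so sizes and states factorize in expectation).
#'
#' @param polls a [simulate_polls()] result (must carry latent truth).
#' @param registry a [hospital_registry()].
#' @param scenario a [build_scenario()] result.
#' @return a `volume_estimate_series`-shaped data.frame of expectations
#'   (`median` holds the expected total; CI columns equal it).
#' @export
truth_volume_series <- function(polls, registry, scenario) {
  truth <- attr(polls, "truth")
  if (is.null(truth)) stop("poll series carries no latent truth")
  baseline_total <- sum(registry$weekly_reference)
  expected <- drop(truth$latent %*% scenario$means) * baseline_total
  out <- data.frame(date = polls$date, median = expected,
                    ci_low = expected, ci_high = expected,
                    percent_of_baseline = expected / baseline_total * 100)
  attr(out, "baseline_total") <- baseline_total
  class(out) <- c("volume_estimate_series", "data.frame")
  out
}

#' Write a complete synthetic fixture set to a directory
#'
#' Produces `polls.csv`, `registry.csv`, `reference.csv`, and `truth.json`
#' (latent distributions, chain, sample sizes, config) so the full pipeline
#' can run from files alone.  The reference series is derived from the
#' analytic expected volumes under the baseline scenario.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, the list of written paths.
#' @export
write_fixtures <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chain <- make_transition_chain(config)
  polls <- simulate_polls(chain, config)
  registry <- make_registry(config)
  truth <- attr(polls, "truth")
  expected <- truth_volume_series(polls, registry, build_scenario("baseline"))
  reference <- make_reference_series(expected, noise_sd = 3,
                                     seed = derive_seeds(config$seed, 4)[4])

  paths <- list(
    polls = file.path(dir, "polls.csv"),
    registry = file.path(dir, "registry.csv"),
    reference = file.path(dir, "reference.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(
    data.frame(date = format(polls$date, "%Y-%m-%d"),
               n1 = polls$n1, n2 = polls$n2, n3 = polls$n3, n4 = polls$n4),
    paths$polls, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(hospital_id = registry$hospital_id,
               annual_ga_count = format(registry$annual_count, digits = 17)),
    paths$registry, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(date = format(reference$date, "%Y-%m-%d"),
               percent = format(reference$percent, digits = 17)),
    paths$reference, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config = unclass(config)[setdiff(names(config), "start_date")],
         start_date = format(config$start_date, "%Y-%m-%d"),
         latent = truth$latent,
         chain = lapply(truth$chain, unclass),
         sample_sizes = truth$sample_sizes),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
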