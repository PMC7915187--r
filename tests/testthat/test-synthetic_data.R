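# Generator properties: band structure, reproducibility, and agreement of
# simulated observations with independently propagated latent truth.

test_that("generated chains are banded, row-stochastic, and identity at zero volatility", {
  cfg0 <- synthetic_config(volatility = 0, seed = 5)
  for (M in make_transition_chain(cfg0)) {
    expect_equal(unclass(M), diag(4), ignore_attr = TRUE)
  }

  cfg <- synthetic_config(volatility = 0.6, seed = 9)
  chain <- make_transition_chain(cfg)
  expect_length(chain, cfg$n_weeks - 1)
  zero_pat <- rbind(c(1, 3), c(1, 4), c(2, 4), c(3, 1), c(4, 1), c(4, 2))
  for (M in chain) {
    expect_equal(rowSums(M), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(unname(M[zero_pat]), rep(0, 6))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("simulated polls follow the propagated latent truth", {
  # identity chain: the latent stays at the all-unrestricted baseline
  cfg0 <- synthetic_config(volatility = 0, seed = 3)
  polls0 <- simulate_polls(make_transition_chain(cfg0), cfg0)
  expect_true(all(poll_proportions(polls0)[, 1] == 1))

  # large samples: observed proportions within 3 binomial SEs of the truth
  # computed by direct matrix propagation (independent of simulate_polls)
  n <- 1e6
  cfg <- synthetic_config(sample_size_range = c(n, n), volatility = 0.4,
                          seed = 11)
  chain <- make_transition_chain(cfg)
  polls <- simulate_polls(chain, cfg)
  lat <- matrix(NA, cfg$n_weeks, 4)
  lat[1, ] <- c(1, 0, 0, 0) %*% chain[[1]]
  for (t in 1:(cfg$n_weeks - 1)) lat[t + 1, ] <- lat[t, ] %*% chain[[t]]
  expect_equal(attr(polls, "truth")$latent, lat, tolerance = 1e-12)
  se <- sqrt(pmax(lat * (1 - lat), 1e-12) / n)
  z <- abs(poll_proportions(polls) - lat) / pmax(se, 1e-12)
  # 68 simultaneous binomial cells: bound the bulk at 3 SE and the max at
  # 4 SE (Bonferroni-adjusted) so the check is sharp but not flaky
  expect_gt(mean(z <= 3), 0.9)
  expect_true(all(z <= 4))

  # default config: weekly totals inside the configured sample-size range
  cfgd <- synthetic_config(seed = 13)
  pd <- simulate_polls(make_transition_chain(cfgd), cfgd)
  totals <- rowSums(as.matrix(pd[paste0("n", 1:4)]))
  expect_true(all(totals >= 47 & totals <= 288))
})

test_that("synthetic registry hits the weekly baseline exactly, above the floor", {
  cfg <- synthetic_config(seed = 21)
  reg <- make_registry(cfg)
  expect_equal(nrow(reg), 1989)
  expect_equal(sum(reg$weekly_reference), 44500, tolerance = 1e-12)
  expect_true(min(reg$annual_count) >= 100)

  one <- make_registry(synthetic_config(n_hospitals = 1, seed = 2))
  expect_equal(one$weekly_reference, 44500)

  # right-skew: top decile of hospitals carries roughly the configured share
  share <- sum(sort(reg$annual_count, decreasing = TRUE)[1:199]) /
    sum(reg$annual_count)
  expect_gt(share, 0.3)
  expect_lt(share, 0.5)
})

test_that("synthetic reference series behaves under noise and shift", {
  est <- data.frame(date = as.Date("2020-03-13") + 7 * (0:16),
                    median = 44500 * seq(1, 0.7, length.out = 17),
                    ci_low = NA, ci_high = NA,
                    percent_of_baseline = 100 * seq(1, 0.7, length.out = 17))
  class(est) <- c("volume_estimate_series", "data.frame")

  ref0 <- make_reference_series(est, noise_sd = 0, shift_days = 0, seed = 1)
  expect_equal(ref0$percent, est$percent_of_baseline, tolerance = 1e-12)
  expect_equal(pearson_oracle(ref0$percent, est$percent_of_baseline), 1,
               tolerance = 1e-12)

  ref3 <- make_reference_series(est, noise_sd = 0, shift_days = 3, seed = 1)
  inside <- ref3$date <= max(est$date)
  manual <- interp_oracle(as.numeric(est$date), est$percent_of_baseline,
                          as.numeric(ref3$date[inside]))
  expect_equal(ref3$percent[inside], manual, tolerance = 1e-12)

  refn <- make_reference_series(est, noise_sd = 50, shift_days = 0, seed = 4)
  expect_lt(pearson_oracle(refn$percent[seq_len(17)],
                           est$percent_of_baseline), 1)
})

test_that("all generator randomness flows from the config seed", {
  cfg <- synthetic_config(seed = 31)
  a <- simulate_polls(make_transition_chain(cfg), cfg)
  b <- simulate_polls(make_transition_chain(cfg), cfg)
  expect_identical(a, b)
  expect_identical(make_registry(cfg), make_registry(cfg))
  cfg2 <- synthetic_config(seed = 32)
  expect_false(identical(make_registry(cfg), make_registry(cfg2)))
})

test_that("fixture writer produces a loadable, truth-carrying set", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_hospitals = 50, seed = 7)
  paths <- write_fixtures(cfg, dir)
  polls <- read_poll_series(paths$polls)
  reg <- read_hospital_registry(paths$registry)
  ref <- read_reference_series(paths$reference)
  expect_equal(nrow(polls), 17)
  expect_equal(nrow(reg), 50)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(dim(truth$latent), c(17, 4))
  expect_equal(dim(truth$chain), c(16, 4, 4))  # simplified to an array
})
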