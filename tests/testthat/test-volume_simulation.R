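# Monte Carlo engine: allocation, evolution, expectation identities, and
# percentile summaries.

small_registry <- function(n = 40, seed = 2) {
  make_registry(synthetic_config(n_hospitals = n,
                                 weekly_baseline_total = 1000, seed = seed))
}

test_that("initial allocation is categorical from y1 and size-independent", {
  reg <- small_registry()
  set.seed(1)
  expect_true(all(allocate_initial(reg, c(1, 0, 0, 0)) == 1))

  big <- hospital_registry(sprintf("h%d", 1:1e5), rep(520, 1e5))
  set.seed(8)
  s <- allocate_initial(big, rep(0.25, 4))
  freq <- tabulate(s, 4) / 1e5
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) <= 3 * se))

  set.seed(42)
  a <- allocate_initial(reg, c(0.3, 0.3, 0.2, 0.2))
  set.seed(42)
  b <- allocate_initial(reg, c(0.3, 0.3, 0.2, 0.2))
  expect_identical(a, b)
})

test_that("state evolution follows the chain and never jumps the band", {
  ident <- constant_chain(diag(4), 9)
  set.seed(3)
  s0 <- sample.int(4, 200, replace = TRUE)
  ev <- evolve_states(s0, ident)
  expect_true(all(ev == s0))  # identity chain freezes states

  # occupancy against the matrix-propagation oracle at large n
  P <- matrix(c(0.7, 0.3, 0, 0, 0.2, 0.6, 0.2, 0,
                0, 0.3, 0.5, 0.2, 0, 0, 0.4, 0.6), 4, 4, byrow = TRUE)
  chain <- constant_chain(P, 6)
  y1 <- c(0.4, 0.3, 0.2, 0.1)
  n <- 1e5
  set.seed(5)
  s <- sample.int(4, n, replace = TRUE, prob = y1)
  ev <- evolve_states(s, chain)
  expected <- y1
  for (t in 2:6) {
    expected <- drop(expected %*% P)
    freq <- tabulate(ev[, t], 4) / n
    se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
    expect_true(all(abs(freq - expected) <= 3 * se + 1e-9))
  }

  # forbidden one-step jumps never occur under random banded chains
  set.seed(9)
  rchain <- lapply(1:8, function(i) transition_matrix(random_banded_matrix()))
  ev2 <- evolve_states(sample.int(4, 500, replace = TRUE), rchain)
  jumps <- cbind(as.vector(ev2[, -ncol(ev2)]), as.vector(ev2[, -1]))
  forbidden <- rbind(c(1, 3), c(1, 4), c(2, 4), c(3, 1), c(4, 1), c(4, 2))
  for (k in seq_len(nrow(forbidden))) {
    expect_false(any(jumps[, 1] == forbidden[k, 1] &
                     jumps[, 2] == forbidden[k, 2]))
  }
})

test_that("pinned-state volumes match the analytic gamma expectation", {
  reg <- small_registry(n = 100)
  sc <- build_scenario("baseline")
  ident <- constant_chain(diag(4), 8)
  run <- simulate_weekly_volumes(reg, ident, c(1, 0, 0, 0), sc,
                                 iterations = 400, seed = 17)
  mu1 <- sc$params[[1]]$shape / sc$params[[1]]$rate  # analytic state-1 mean
  expected <- sum(reg$weekly_reference) * mu1
  m <- rowMeans(run$weekly_totals)
  se <- apply(run$weekly_totals, 1, stats::sd) / sqrt(run$iterations)
  expect_true(all(abs(m - expected) <= 3 * se))
})

test_that("runs are reproducible and degenerate inputs behave", {
  reg <- small_registry()
  cfg <- synthetic_config(n_weeks = 6, seed = 4, volatility = 0.4)
  chain <- make_transition_chain(cfg)
  sc <- build_scenario("baseline")
  y1 <- c(0.7, 0.2, 0.1, 0)
  a <- simulate_weekly_volumes(reg, chain, y1, sc, iterations = 50, seed = 6)
  b <- simulate_weekly_volumes(reg, chain, y1, sc, iterations = 50, seed = 6)
  expect_identical(a$weekly_totals, b$weekly_totals)

  empty <- hospital_registry(character(0), numeric(0))
  r0 <- simulate_weekly_volumes(empty, chain, y1, sc, iterations = 5, seed = 1)
  expect_true(all(r0$weekly_totals == 0))

  fixed <- simulate_weekly_volumes(reg, chain, y1, sc, iterations = 20,
                                   seed = 6, reallocate = FALSE,
                                   keep_states = TRUE)
  expect_equal(dim(fixed$states), c(nrow(reg), 6, 20))
  expect_true(all(fixed$states[, 1, 1] == fixed$states[, 1, 20]))
})

test_that("summaries use interpolated percentiles and baseline percent", {
  reg <- small_registry()
  base_total <- sum(reg$weekly_reference)

  run <- structure(list(weekly_totals = matrix(base_total * 0.671, 3, 10),
                        dates = as.Date("2020-03-13") + 7 * (0:2),
                        iterations = 10L, seed = 1L, scenario = "baseline",
                        baseline_total = base_total),
                   class = "simulation_run")
  s <- summarize_volumes(run, reg)
  expect_equal(s$percent_of_baseline, rep(67.1, 3), tolerance = 1e-12)
  expect_equal(s$ci_low, s$ci_high)  # constant draws: zero-width CI

  set.seed(30)
  vals <- matrix(rnorm(5 * 200, 1000, 50), 5, 200)
  run2 <- structure(list(weekly_totals = vals, dates = NULL,
                         iterations = 200L, seed = 1L, scenario = "baseline",
                         baseline_total = base_total),
                    class = "simulation_run")
  s2 <- summarize_volumes(run2, reg)
  for (t in 1:5) {
    srt <- sort(vals[t, ])
    # type-7 percentile oracle: linear interpolation of order statistics
    q <- function(p) {
      h <- (length(srt) - 1) * p + 1
      srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
    }
    expect_equal(s2$median[t], q(0.5), tolerance = 1e-12)
    expect_equal(s2$ci_low[t], q(0.025), tolerance = 1e-12)
    expect_equal(s2$ci_high[t], q(0.975), tolerance = 1e-12)
    expect_true(s2$ci_low[t] <= s2$median[t] && s2$median[t] <= s2$ci_high[t])
  }
})
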