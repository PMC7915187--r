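# Independent oracles and small generators used across the suite.  These
# deliberately re-derive quantities by different routes than the package
# (exhaustive enumeration, closed forms, hand-rolled interpolation) so that
# agreement is evidence, not tautology.

# band bookkeeping, restated independently of the package internals
ORC_FREE_ROW <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
ORC_FREE_COL <- c(1L, 2L, 1L, 2L, 3L, 2L, 3L, 4L, 3L, 4L)

orc_free_to_matrix <- function(p) {
  P <- matrix(0, 4, 4)
  P[cbind(ORC_FREE_ROW, ORC_FREE_COL)] <- p
  P
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# random banded row-stochastic matrix, rows Dirichlet over allowed entries
random_banded_matrix <- function(conc = 1) {
  p <- numeric(10)
  for (r in 1:4) {
    k <- which(ORC_FREE_ROW == r)
    p[k] <- rdirichlet1(rep(conc, length(k)))
  }
  orc_free_to_matrix(p)
}

# a random estimation window: three loosely related proportion vectors
random_window <- function() {
  y_prev <- rdirichlet1(rep(1, 4))
  P1 <- random_banded_matrix()
  P2 <- random_banded_matrix()
  y_curr <- rdirichlet1(50 * drop(y_prev %*% P1) + 0.05)
  y_next <- rdirichlet1(50 * drop(y_curr %*% P2) + 0.05)
  build_qp_window(y_prev, y_curr, y_next)
}

# Exhaustive-enumeration oracle for the transition QP: solves the identical
# ridged objective by checking the KKT point of every subset of active
# bounds (2^10 candidates) and keeping the feasible candidate with the
# lowest objective.  Exact for a strictly convex QP; independent of the
# package's iterative active-set path.
brute_force_qp <- function(window, ridge = 1e-12, prior = diag(4)) {
  X <- window$design
  y <- window$target
  XtX <- crossprod(X)
  ridge_abs <- max(ridge * sum(diag(XtX)), 1e-12)
  D <- XtX + ridge_abs * diag(10)
  d <- drop(crossprod(X, y)) + ridge_abs * prior[cbind(ORC_FREE_ROW,
                                                       ORC_FREE_COL)]
  A_eq <- matrix(0, 4, 10)
  A_eq[cbind(ORC_FREE_ROW, seq_len(10))] <- 1

  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^10 - 1)) {
    act <- which(bitwAnd(mask, 2^(0:9)) > 0)
    A <- rbind(A_eq, diag(10)[act, , drop = FALSE])
    k <- nrow(A)
    K <- rbind(cbind(D, t(A)), cbind(A, matrix(0, k, k)))
    sol <- tryCatch(solve(K, c(d, rep(1, 4), rep(0, length(act)))),
                    error = function(e) NULL)
    if (is.null(sol)) next
    p <- sol[1:10]
    if (any(p < -1e-9)) next
    obj <- 0.5 * sum(p * (D %*% p)) - sum(d * p)
    if (obj < best_obj) {
      best_obj <- obj
      best <- p
    }
  }
  list(solution = best, objective = best_obj, ridge_abs = ridge_abs)
}

# unridged squared misfit of a banded matrix on a window
window_misfit <- function(window, P) {
  p <- P[cbind(ORC_FREE_ROW, ORC_FREE_COL)]
  sum((window$target - window$design %*% p)^2)
}

# hand-rolled piecewise-linear interpolation
interp_oracle <- function(x, y, xq) {
  vapply(xq, function(q) {
    i <- findInterval(q, x, rightmost.closed = TRUE)
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# textbook product-moment correlation
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

constant_chain <- function(P, n_weeks) {
  lapply(seq_len(n_weeks - 1L), function(i) transition_matrix(P))
}

# persistently exciting test matrix for recovery experiments: a chain that
# damps to stationarity makes late windows uninformative (consecutive poll
# distributions coincide), so the designed experiment uses a near-permutation
# matrix whose oscillation keeps every window well conditioned
recovery_P <- function() {
  matrix(c(0.05, 0.95, 0,    0,
           0.90, 0.05, 0.05, 0,
           0,    0.90, 0.05, 0.05,
           0,    0,    0.95, 0.05), 4, 4, byrow = TRUE)
}

# max estimation error over identifiable entries (source occupancy >= 0.05
# in either stacked window row), against a constant truth P
recovery_error <- function(sample_size, seed, P = recovery_P()) {
  cfg <- synthetic_config(n_weeks = 17,
                          sample_size_range = c(sample_size, sample_size),
                          seed = seed)
  polls <- simulate_polls(constant_chain(P, 17), cfg)
  chain <- estimate_transition_chain(polls)
  Yfull <- rbind(c(1, 0, 0, 0), poll_proportions(polls))
  err <- 0
  for (t in 1:16) {
    ident <- pmax(Yfull[t, ], Yfull[t + 1, ]) >= 0.05
    err <- max(err, max(abs(chain$matrices[[t]] - P)[ident, , drop = FALSE]))
  }
  err
}
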