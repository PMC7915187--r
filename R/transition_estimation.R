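# Ecological inference of weekly restriction-state transitions.
#
# Individual hospitals are never tracked; each poll gives only the aggregate
# distribution y_t over the four states.  Writing the one-step evolution as
# y_{j,t+1} = sum_i y_{i,t} p_{ij,t} + noise and stacking two consecutive
# steps (t-1 -> t and t -> t+1, so the system is not hopelessly
# underdetermined) gives a least-squares problem in the 10 free banded
# transition parameters, solved as a quadratic program under row-sum and
# [0,1] constraints.

#' Construct a banded transition matrix object
#'
#' Validates the birth-death band (no jumps across a severity level in one
#' week), row-stochasticity, and entry bounds, then re-normalizes rows to
#' sum exactly 1.
#'
#' @param P 4x4 numeric matrix.
#' @param tol allowed violation of bounds / row sums before cleanup.
#' @return a `transition_matrix` (4x4 matrix with class attribute).
#' @export
transition_matrix <- function(P, tol = 1e-8) {
  P <- as.matrix(P)
  stopifnot(all(dim(P) == N_STATES))
  if (max(abs(P[!BAND_ALLOWED])) > 0) {
    stop("transition matrix violates the banded zero pattern")
  }
  if (min(P) < -tol || max(P) > 1 + tol) {
    stop("transition entries outside [0,1] beyond tolerance")
  }
  if (max(abs(rowSums(P) - 1)) > tol) {
    stop("transition rows do not sum to 1 within tolerance")
  }
  P <- pmin(pmax(P, 0), 1)
  P <- P / rowSums(P)
  P[!BAND_ALLOWED] <- 0  # exact zeros survive the clip, keep them exact
  structure(P, class = c("transition_matrix", "matrix", "array"))
}

#' Banded identity matrix (full persistence)
#' @return the identity as a [transition_matrix()].
#' @export
identity_transition <- function() {
  transition_matrix(diag(N_STATES))
}

#' Build the stacked two-window quadratic-program data for one week
#'
#' For estimation index t the two transitions t-1 -> t and t -> t+1 are
#' stacked, assuming the matrix is locally constant across them.  The design
#' maps the 10 free banded parameters to the 8 predicted destination
#' proportions; the target stacks the observed proportions in the order
#' (destination 1 at t, destination 1 at t+1, destination 2 at t, ...).
#'
#' @param y_prev,y_curr,y_next length-4 proportion vectors for weeks t-1, t,
#'   t+1; each must sum to 1 within 1e-6.
#' @return a `qp_window`: list with `design` (8x10), `target` (length 8),
#'   `A_eq` (4x10 row-sum constraints), `b_eq` (all 1), and the three input
#'   vectors.
#' @export
build_qp_window <- function(y_prev, y_curr, y_next) {
  check <- function(y, nm) {
    if (length(y) != N_STATES) stop(nm, " must have length 4")
    if (abs(sum(y) - 1) > 1e-6) stop(nm, " does not sum to 1")
    if (any(y < 0)) stop(nm, " has negative entries")
  }
  check(y_prev, "y_prev"); check(y_curr, "y_curr"); check(y_next, "y_next")

  design <- matrix(0, 2L * N_STATES, N_FREE)
  target <- numeric(2L * N_STATES)
  sources <- list(y_prev, y_curr)
  observed <- list(y_curr, y_next)
  for (j in seq_len(N_STATES)) {
    for (w in 1:2) {
      r <- 2L * (j - 1L) + w
      k <- which(FREE_COL == j)
      design[r, k] <- sources[[w]][FREE_ROW[k]]
      target[r] <- observed[[w]][j]
    }
  }
  structure(list(design = design, target = target,
                 A_eq = band_equality_matrix(), b_eq = rep(1, N_STATES),
                 y_prev = y_prev, y_curr = y_curr, y_next = y_next),
            class = "qp_window")
}

#' Solve the transition quadratic program for one window
#'
#' Minimizes the squared misfit `||target - design %*% p||^2` over the free
#' banded parameters, subject to row sums of 1 and entries in `[0, 1]`.  A
#' small ridge toward a persistence prior keeps the problem strictly convex
#' (the stacked system has 8 equations and 10 unknowns) and pins down rows
#' whose source state has (near-)zero occupancy in the window and is
#' therefore not informed by the data; it vanishes as data accumulate.
#'
#' @param window a [build_qp_window()] result.
#' @param ridge non-negative ridge strength, relative to `trace(X'X)`; the
#'   absolute ridge added to the Hessian is `ridge * trace(X'X)` (with a
#'   floor of `1e-12` so the Hessian is always positive definite).
#' @param prior [transition_matrix()] toward which unidentified entries are
#'   pulled; defaults to the banded identity (persistence).
#' @return list with `matrix` (cleaned [transition_matrix()], after a
#'   ridge-free re-solve on the optimal face when that system is
#'   nonsingular), `raw` (unclipped ridged solution matrix), `objective`
#'   (unridged squared misfit of the cleaned solution), `solver` (the
#'   [solve_qp()] record).
#' @export
solve_transition_qp <- function(window, ridge = 1e-12,
                                prior = identity_transition()) {
  stopifnot(inherits(window, "qp_window"), ridge >= 0)
  X <- window$design
  y <- window$target
  XtX <- crossprod(X)
  ridge_abs <- max(ridge * sum(diag(XtX)), 1e-12)
  D <- XtX + ridge_abs * diag(N_FREE)
  d <- drop(crossprod(X, y)) + ridge_abs * matrix_to_free(prior)

  # uniform-within-band start: strictly feasible for every working set
  start <- 1 / tabulate(FREE_ROW)[FREE_ROW]
  sol <- solve_qp(D, d, window$A_eq, window$b_eq, start)

  # polish: re-solve ridge-free on the optimal face so an exactly
  # consistent window is recovered to machine precision rather than with
  # the O(ridge / sigma_min^2) bias of the regularized solution; kept only
  # when the face system is nonsingular and the step is a small correction
  p_hat <- sol$solution
  A_face <- rbind(window$A_eq, diag(N_FREE)[sol$active, , drop = FALSE])
  k <- nrow(A_face)
  K0 <- rbind(cbind(XtX, t(A_face)), cbind(A_face, matrix(0, k, k)))
  rhs0 <- c(drop(crossprod(X, y)), window$b_eq, rep(0, length(sol$active)))
  polish <- tryCatch(solve(K0, rhs0)[seq_len(N_FREE)],
                     error = function(e) NULL)
  if (!is.null(polish) && all(is.finite(polish)) &&
      min(polish) > -1e-9 && max(polish) < 1 + 1e-9 &&
      max(abs(polish - p_hat)) < 1e-2) {
    p_hat <- polish
  }

  raw <- free_to_matrix(sol$solution)
  cleaned <- transition_matrix(free_to_matrix(p_hat), tol = 1e-8)
  resid <- y - X %*% matrix_to_free(cleaned)
  list(matrix = cleaned, raw = raw, objective = sum(resid^2),
       ridge_abs = ridge_abs, solver = sol)
}

#' Estimate the weekly transition chain from a poll series
#'
#' For each estimation index t = 1..T-1 (T poll dates), the matrix P_t is
#' estimated from the window (y_{t-1}, y_t, y_{t+1}), with y_0 the
#' pre-survey baseline distribution.  Fitted proportions are one-step-ahead
#' predictions from the observed previous week.
#'
#' @param polls a [poll_series()] with at least 3 dates.
#' @param ridge relative ridge strength, see [solve_transition_qp()].
#' @param prior persistence prior, see [solve_transition_qp()].
#' @return a `transition_chain`: list with `matrices` (length T-1 list of
#'   [transition_matrix()]), `dates` (poll dates), `fitted` (T x 4 matrix of
#'   one-step-ahead proportions, row t predicting the poll at date t),
#'   `objectives` (per-window unridged misfits), `baseline`.
#' @export
estimate_transition_chain <- function(polls, ridge = 1e-12,
                                      prior = identity_transition()) {
  stopifnot(inherits(polls, "poll_series"))
  Y <- poll_proportions(polls)
  T_n <- nrow(Y)
  if (T_n < 3) stop("need at least 3 poll dates to estimate transitions")
  baseline <- attr(polls, "baseline")
  Yfull <- rbind(baseline, Y)  # row 1 is t = 0

  matrices <- vector("list", T_n - 1L)
  objectives <- numeric(T_n - 1L)
  for (t in seq_len(T_n - 1L)) {
    w <- build_qp_window(Yfull[t, ], Yfull[t + 1L, ], Yfull[t + 2L, ])
    fit <- solve_transition_qp(w, ridge = ridge, prior = prior)
    matrices[[t]] <- fit$matrix
    objectives[t] <- fit$objective
  }

  fitted <- matrix(NA_real_, T_n, N_STATES)
  for (t in seq_len(T_n - 1L)) {
    fitted[t, ] <- drop(Yfull[t, ] %*% matrices[[t]])
  }
  fitted[T_n, ] <- drop(Yfull[T_n, ] %*% matrices[[T_n - 1L]])
  fitted <- fitted / rowSums(fitted)

  structure(list(matrices = matrices, dates = polls$date, fitted = fitted,
                 objectives = objectives, baseline = baseline, ridge = ridge),
            class = "transition_chain")
}

#' Forward-propagate a state distribution through a transition chain
#'
#' Chained propagation from a starting distribution: row t of the result is
#' the distribution after t-1 applications of the chain, so row 1 is
#' `start` itself.
#'
#' @param chain a `transition_chain` or plain list of 4x4 matrices.
#' @param start length-4 probability vector.
#' @param n_steps number of matrices to apply (default: all).
#' @return `(n_steps + 1) x 4` matrix of distributions.
#' @export
propagate_chain <- function(chain, start, n_steps = NULL) {
  mats <- if (inherits(chain, "transition_chain")) chain$matrices else chain
  if (is.null(n_steps)) n_steps <- length(mats)
  stopifnot(n_steps <= length(mats), length(start) == N_STATES)
  out <- matrix(NA_real_, n_steps + 1L, N_STATES)
  out[1, ] <- start
  for (t in seq_len(n_steps)) {
    out[t + 1L, ] <- drop(out[t, ] %*% mats[[t]])
  }
  out
}

#' @export
print.transition_chain <- function(x, ...) {
  cat(sprintf("transition_chain: %d weekly 4x4 banded matrices (%s .. %s)\n",
              length(x$matrices), min(x$dates), max(x$dates)))
  cat(sprintf("  total unridged misfit: %.3g\n", sum(x$objectives)))
  invisible(x)
}
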