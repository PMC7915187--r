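# Dense primal active-set solver for the small strictly convex quadratic
# programs arising in transition estimation:
#
#     minimize  1/2 p' D p - d' p
#     s.t.      A_eq p = b_eq,   p >= 0
#
# With D symmetric positive definite (the estimation code guarantees this by
# adding a ridge), each equality-constrained subproblem has a unique solution
# obtained from the KKT system; bounds enter and leave a working set until
# all multipliers have the optimal sign.  Problems here have 10 variables and
# 4 equality constraints, so no sparse machinery is warranted.

#' Solve a strictly convex quadratic program with equality and
#' non-negativity constraints
#'
#' @param D symmetric positive definite matrix (n x n).
#' @param d linear term (length n); the objective is `0.5 p'Dp - d'p`.
#' @param A_eq equality constraint matrix (m x n), full row rank.
#' @param b_eq equality right-hand side (length m).
#' @param start feasible starting point (`A_eq start = b_eq`, `start >= 0`).
#' @param max_iter working-set iteration cap.
#' @return list with `solution`, `objective` (of the quadratic above),
#'   `iterations`, `status` (`"optimal"` or an error is thrown).
#' @export
solve_qp <- function(D, d, A_eq, b_eq, start, max_iter = 200L) {
  n <- length(d)
  m <- nrow(A_eq)
  stopifnot(nrow(D) == n, ncol(D) == n, ncol(A_eq) == n, length(b_eq) == m)
  p <- as.numeric(start)
  if (max(abs(A_eq %*% p - b_eq)) > 1e-9 || any(p < -1e-12)) {
    stop("solve_qp: start point infeasible")
  }
  active <- which(p <= 1e-14)  # working set of bounds held at zero

  kkt_solve <- function(active) {
    A <- rbind(A_eq, diag(n)[active, , drop = FALSE])
    k <- nrow(A)
    K <- rbind(cbind(D, t(A)), cbind(A, matrix(0, k, k)))
    rhs <- c(d, b_eq, rep(0, length(active)))
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    list(p = sol[seq_len(n)], lambda = sol[n + seq_len(k)])
  }

  for (iter in seq_len(max_iter)) {
    sub <- kkt_solve(active)
    if (is.null(sub)) {
      # dependent working set (can arise from degenerate starts); drop the
      # most recently added bound and retry
      if (length(active) == 0) stop("solve_qp: singular KKT system")
      active <- active[-length(active)]
      next
    }
    step <- sub$p - p
    if (max(abs(step)) < 1e-11) {
      # stationary on the working set: check bound multipliers.
      # Stationarity is D p - d + A' lambda = 0; for a bound row e_k the
      # KKT multiplier of p_k >= 0 is -lambda_k, so optimality needs
      # lambda_k <= 0 on every active bound.
      lam_bounds <- sub$lambda[m + seq_along(active)]
      if (length(active) == 0 || max(lam_bounds) <= 1e-9) {
        obj <- 0.5 * sum(p * (D %*% p)) - sum(d * p)
        return(list(solution = p, objective = obj, active = active,
                    iterations = iter, status = "optimal"))
      }
      active <- active[-which.max(lam_bounds)]
    } else {
      # line search to the nearest bound not in the working set
      free <- setdiff(which(step < -1e-14), active)
      alpha <- 1
      block <- NA_integer_
      if (length(free) > 0) {
        ratios <- -p[free] / step[free]
        j <- which.min(ratios)
        if (ratios[j] < alpha) {
          alpha <- ratios[j]
          block <- free[j]
        }
      }
      p <- p + alpha * step
      if (!is.na(block)) {
        p[block] <- 0
        active <- sort(c(active, block))
      }
    }
  }
  stop("solve_qp: working-set iteration limit reached")
}
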