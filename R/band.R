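#' @keywords internal
"_PACKAGE"

# Restriction states form an ordered severity scale; in one week a hospital
# can only move to an adjacent severity level (a birth-death chain), so the
# 4x4 transition matrix is banded: entries (1,3),(1,4),(2,4),(3,1),(4,1),(4,2)
# are structurally zero.  The 10 free entries, in row-major order, are the
# canonical parameter vector used throughout the quadratic program.

#' Number of restriction states
#' @keywords internal
N_STATES <- 4L

#' Logical mask of allowed (banded) transitions
#' @keywords internal
BAND_ALLOWED <- matrix(c(
  TRUE,  TRUE,  FALSE, FALSE,
  TRUE,  TRUE,  TRUE,  FALSE,
  FALSE, TRUE,  TRUE,  TRUE,
  FALSE, FALSE, TRUE,  TRUE
), nrow = 4, byrow = TRUE)

# Source row / destination column of each free parameter, row-major:
# p11 p12 p21 p22 p23 p32 p33 p34 p43 p44
FREE_ROW <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
FREE_COL <- c(1L, 2L, 1L, 2L, 3L, 2L, 3L, 4L, 3L, 4L)
N_FREE <- 10L

#' Expand the 10 free transition parameters into a 4x4 banded matrix
#'
#' @param p numeric vector of length 10, the free entries in row-major order
#'   (`p11, p12, p21, p22, p23, p32, p33, p34, p43, p44`).
#' @return a 4x4 numeric matrix with the structural zeros in place.
#' @keywords internal
free_to_matrix <- function(p) {
  stopifnot(length(p) == N_FREE)
  P <- matrix(0, N_STATES, N_STATES)
  P[cbind(FREE_ROW, FREE_COL)] <- p
  P
}

#' Extract the 10 free parameters from a banded 4x4 matrix
#' @param P 4x4 numeric matrix.
#' @keywords internal
matrix_to_free <- function(P) {
  P[cbind(FREE_ROW, FREE_COL)]
}

#' Row-sum equality constraint matrix over the free parameters
#'
#' Each restriction state's outgoing probabilities must sum to 1; over the
#' free parameter vector this is a 4x10 indicator matrix.
#' @keywords internal
band_equality_matrix <- function() {
  A <- matrix(0, N_STATES, N_FREE)
  A[cbind(FREE_ROW, seq_len(N_FREE))] <- 1
  A
}

#' Deterministic sub-seed derivation
#'
#' Spawns reproducible per-stage seeds from one master seed so that adding a
#' stage (for example a scenario) does not perturb another stage's draws.
#' Returned seeds are strictly below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
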