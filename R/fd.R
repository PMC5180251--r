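#' Finite-difference differentiation matrix on a uniform grid
#'
#' Second-order accurate differentiation matrices used by the
#' finite-difference discretization that cross-checks the differential
#' quadrature solver. Interior rows carry the classical central stencils
#' (`(-1, 0, 1)/2h` and `(1, -2, 1)/h^2`); boundary rows carry one-sided
#' second-order stencils so that traction boundary conditions can be
#' collocated at the wall surfaces without losing order.
#'
#' Kept deliberately separate from [dqm_weights()]: the two code paths share
#' nothing beyond base arithmetic, so agreement between the solvers built on
#' them is a meaningful check.
#'
#' @param n number of grid points (>= 3 for first order, >= 4 for second).
#' @param h uniform grid spacing.
#' @param order derivative order, 1 or 2.
#' @return dense n x n differentiation matrix.
#' @export
fd_diff_matrix <- function(n, h, order = 1) {
  if (n < 3) stop("at least three points required", call. = FALSE)
  if (!order %in% c(1, 2)) stop("derivative order must be 1 or 2", call. = FALSE)
  D <- matrix(0, n, n)
  if (order == 1) {
    for (i in 2:(n - 1)) {
      D[i, i - 1] <- -1 / (2 * h); D[i, i + 1] <- 1 / (2 * h)
    }
    D[1, 1:3] <- c(-3, 4, -1) / (2 * h)
    D[n, (n - 2):n] <- c(1, -4, 3) / (2 * h)
  } else {
    if (n < 4) stop("at least four points required for second derivatives", call. = FALSE)
    for (i in 2:(n - 1)) {
      D[i, (i - 1):(i + 1)] <- c(1, -2, 1) / h^2
    }
    D[1, 1:4] <- c(2, -5, 4, -1) / h^2
    D[n, (n - 3):n] <- c(-1, 4, -5, 2) / h^2
  }
  D
}
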