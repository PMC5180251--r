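#' Chebyshev-Gauss-Lobatto collocation nodes on [0, 1]
#'
#' `x_i = (1 - cos(i*pi/(n-1))) / 2`, i = 0..n-1. The cosine clustering near
#' both endpoints is the standard stable sampling for differential
#' quadrature; it resolves the bending boundary layers at the fixed vessel
#' ends without extra points.
#'
#' @param n number of nodes, >= 2.
#' @return strictly increasing numeric vector with endpoints 0 and 1.
#' @export
cgl_nodes <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("node count must be an integer >= 2", call. = FALSE)
  }
  i <- 0:(n - 1)
  x <- (1 - cos(i * pi / (n - 1))) / 2
  x[1] <- 0; x[n] <- 1
  x
}

#' Differential quadrature weighting matrix
#'
#' Lagrange-interpolation derivative weights on an arbitrary set of distinct
#' nodes: `(D f)(x_i) = sum_j D[i,j] f(x_j)` is exact for polynomials up to
#' degree n-1. Off-diagonal first-order weights use the product formula
#' `a_ij = P(x_i) / ((x_i - x_j) P'(x_j))` with `P(x_i) = prod_{k != i}
#' (x_i - x_k)`; diagonals are the negative row sums (a constant has zero
#' derivative). Second-order weights use the standard recurrence
#' `b_ij = 2 a_ij (a_ii - 1/(x_i - x_j))`, or `D1 %*% D1` when
#' `method = "product"`.
#'
#' @param nodes strictly increasing numeric vector of distinct nodes.
#' @param order derivative order, 1 or 2.
#' @param method for `order = 2`: `"recurrence"` (default) or `"product"`.
#' @return dense n x n weighting matrix.
#' @export
dqm_weights <- function(nodes, order = 1, method = c("recurrence", "product")) {
  method <- match.arg(method)
  n <- length(nodes)
  if (n < 2) stop("at least two nodes required", call. = FALSE)
  if (any(diff(nodes) <= 0)) stop("nodes must be distinct and increasing", call. = FALSE)
  if (!order %in% c(1, 2)) stop("derivative order must be 1 or 2", call. = FALSE)

  diffs <- outer(nodes, nodes, "-")          # x_i - x_j
  diag(diffs) <- 1
  logP <- rowSums(log(abs(diffs)))           # log prod_{k!=i} |x_i - x_k|
  sgnP <- apply(sign(diffs), 1L, prod)       # products are small; logs avoid underflow
  D1 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    D1[i, j] <- sgnP[i] * sgnP[j] * exp(logP[i] - logP[j]) / diffs[i, j]
  }
  diag(D1) <- -rowSums(D1)
  if (order == 1) return(D1)

  if (method == "product") return(D1 %*% D1)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    D2[i, j] <- 2 * D1[i, j] * (diag(D1)[i] - 1 / diffs[i, j])
  }
  diag(D2) <- -rowSums(D2)
  D2
}

#' Collocation grid with derivative weighting matrices
#'
#' Bundles the 1D node set on [0, 1] with its first- and second-derivative
#' weighting matrices, either spectral differential quadrature (`"dqm"`,
#' CGL or uniform nodes, dense Lagrange weights) or second-order central
#' finite differences (`"fd"`, uniform nodes) which serves as the fully
#' independent cross-check discretization.
#'
#' @param n number of nodes per direction.
#' @param method `"dqm"` or `"fd"`.
#' @param family node family for DQM: `"cgl"` (default) or `"uniform"`.
#' @return An object of class `fgm_grid1d` with fields `nodes`, `D1`, `D2`,
#'   `n`, `method` (all on the unit interval; scale by 1/h, 1/h^2 for a
#'   physical interval of length h).
#' @export
grid1d <- function(n, method = c("dqm", "fd"), family = c("cgl", "uniform")) {
  method <- match.arg(method)
  family <- match.arg(family)
  if (method == "dqm") {
    nodes <- if (family == "cgl") cgl_nodes(n) else seq(0, 1, length.out = n)
    D1 <- dqm_weights(nodes, 1)
    D2 <- dqm_weights(nodes, 2)
  } else {
    nodes <- seq(0, 1, length.out = n)
    h <- 1 / (n - 1)
    D1 <- fd_diff_matrix(n, h, 1)
    D2 <- fd_diff_matrix(n, h, 2)
  }
  structure(list(nodes = nodes, D1 = D1, D2 = D2, n = n, method = method),
            class = "fgm_grid1d")
}
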