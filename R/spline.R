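#' Order-d difference penalty matrix
#'
#' Builds the P-spline wiggliness penalty `S = t(D) %*% D`, where `D` is the
#' `(K - d) x K` matrix of order-`d` forward differences of adjacent basis
#' coefficients. `S` is symmetric positive semidefinite with rank `K - d`;
#' its null space is spanned by polynomial coefficient sequences of degree
#' `d - 1`.
#'
#' @param n_basis Number of basis functions `K`.
#' @param order Difference order `d` (`1 <= d < K`). Default 2.
#' @return A `K x K` penalty matrix.
#' @export
difference_penalty <- function(n_basis, order = 2) {
  stopifnot(n_basis >= 2, order >= 1)
  if (order >= n_basis) abort("difference order must be smaller than n_basis")
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}

#' Construct a penalized B-spline (P-spline) basis
#'
#' Sets up a B-spline basis of the given polynomial degree over a stated
#' angle domain, with uniformly spaced interior knots and
#' degree-plus-one-fold replicated boundary knots, together with an order-`d`
#' difference penalty and its mixed-model reparameterization. The basis
#' functions are evaluated by the Cox--de Boor recursion; they are
#' nonnegative and sum to one at every point of the domain (partition of
#' unity).
#'
#' The reparameterization eigendecomposes the penalty `S = U L t(U)`. The
#' `d` eigenvectors with (numerically) zero eigenvalue span the unpenalized
#' polynomial part; the remaining `K - d` directions, scaled by
#' `1/sqrt(lambda)`, become columns on which a unit ridge penalty is
#' equivalent to the original smoothing penalty, so smoothing reduces to
#' estimating a single variance component.
#'
#' @param domain Length-2 numeric, the closed interval covered by the basis.
#'   Default `c(0, 90)` degrees of knee flexion.
#' @param n_basis Number of basis functions `K` (`>= degree + 1`). Default 12.
#' @param degree Polynomial degree. Default 3 (cubic).
#' @param penalty_order Difference order `d` of the penalty. Default 2.
#' @return An object of class `"smooth_basis"`: a list with elements
#'   `domain`, `knots`, `degree`, `n_basis`, `penalty_order`, `penalty`
#'   (the `K x K` matrix), `U0` (`K x d` null-space eigenvectors), `Up` and
#'   `lambda` (positive eigenpairs).
#' @seealso [eval_basis()], [basis_design()], [difference_penalty()]
#' @export
smooth_basis <- function(domain = c(0, 90), n_basis = 12, degree = 3,
                         penalty_order = 2) {
  stopifnot(length(domain) == 2, is.numeric(domain))
  if (!(domain[2] > domain[1])) abort("domain must be nondegenerate (lo < hi)")
  if (n_basis < degree + 1) abort("n_basis must be at least degree + 1")
  n_interior <- n_basis - degree - 1
  interior <- if (n_interior > 0) {
    seq(domain[1], domain[2], length.out = n_interior + 2)[-c(1, n_interior + 2)]
  } else numeric(0)
  knots <- c(rep(domain[1], degree + 1), interior, rep(domain[2], degree + 1))
  S <- difference_penalty(n_basis, penalty_order)
  eg <- eigen(S, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  if (any(eg$values < -tol)) {
    abort("penalty eigendecomposition produced negative eigenvalues beyond tolerance")
  }
  pos <- eg$values > tol
  if (sum(!pos) != penalty_order) {
    abort("penalty null-space dimension does not equal the difference order")
  }
  structure(list(
    domain = domain, knots = knots, degree = degree, n_basis = n_basis,
    penalty_order = penalty_order, penalty = S,
    U0 = eg$vectors[, !pos, drop = FALSE],
    Up = eg$vectors[, pos, drop = FALSE],
    lambda = eg$values[pos]
  ), class = "smooth_basis")
}

#' @export
print.smooth_basis <- function(x, ...) {
  cat("P-spline basis: K =", x$n_basis, ", degree =", x$degree,
      ", penalty order =", x$penalty_order,
      ", domain = [", x$domain[1], ",", x$domain[2], "]\n")
  invisible(x)
}

# Cox--de Boor recursion over the padded knot vector. Returns n x K matrix.
# The right domain endpoint is assigned to the last nonempty interval so the
# partition of unity holds on the closed domain.
cox_de_boor <- function(x, knots, degree, n_basis) {
  n <- length(x)
  # degree-0: indicator of the half-open knot interval [t_j, t_{j+1}),
  # closed at the right boundary
  n_int <- length(knots) - 1
  B <- matrix(0, n, n_int)
  right <- knots[length(knots)]
  for (j in seq_len(n_int)) {
    if (knots[j + 1] > knots[j]) {
      B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
    }
  }
  last_nonempty <- max(which(diff(knots) > 0))
  B[x == right, last_nonempty] <- 1
  if (degree == 0) return(B[, seq_len(n_basis), drop = FALSE])
  for (p in seq_len(degree)) {
    ncol_new <- n_int - p
    Bnew <- matrix(0, n, ncol_new)
    for (j in seq_len(ncol_new)) {
      d1 <- knots[j + p] - knots[j]
      d2 <- knots[j + p + 1] - knots[j + 1]
      term <- 0
      if (d1 > 0) term <- term + (x - knots[j]) / d1 * B[, j]
      if (d2 > 0) term <- term + (knots[j + p + 1] - x) / d2 * B[, j + 1]
      Bnew[, j] <- term
    }
    B <- Bnew
  }
  B[, seq_len(n_basis), drop = FALSE]
}

#' Evaluate a smooth basis at a set of points
#'
#' @param basis A `"smooth_basis"` object from [smooth_basis()].
#' @param x Numeric vector of evaluation points; must lie within the basis
#'   domain (no extrapolation).
#' @return An `length(x) x K` matrix of basis function values.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "smooth_basis"))
  if (any(x < basis$domain[1] | x > basis$domain[2])) {
    abort(paste0("evaluation points outside the basis domain [",
                 basis$domain[1], ", ", basis$domain[2], "]"))
  }
  cox_de_boor(x, basis$knots, basis$degree, basis$n_basis)
}

#' Mixed-model design columns of a smooth
#'
#' Evaluates the reparameterized design at `x`: the unpenalized polynomial
#' part `X0 = B %*% U0` (one column per penalty null-space dimension) and the
#' penalized part `Z = B %*% Up %*% diag(1/sqrt(lambda))`, whose
#' coefficients act as independent zero-mean random effects with a common
#' variance. A ridge penalty of 1 on the `Z` coefficients reproduces the
#' original difference penalty `lambda * t(beta) %*% S %*% beta` up to the
#' variance-component parameterization (`lambda = 1 / tau^2`).
#'
#' @inheritParams eval_basis
#' @return A list with matrices `X0` (`n x d`) and `Z` (`n x (K - d)`).
#' @export
basis_design <- function(basis, x) {
  B <- eval_basis(basis, x)
  list(X0 = B %*% basis$U0,
       Z = B %*% basis$Up %*% diag(1 / sqrt(basis$lambda),
                                   nrow = length(basis$lambda)))
}
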