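#' Zero the diagonal of a square parameter matrix
#'
#' The regression parameterizations of neighborhood and Markov networks
#' never allow a gene to predict itself, so the diagonal of the parameter
#' matrix is masked to exactly zero before it enters a loss:
#' \eqn{\theta' = (1 - I) \odot \theta}.
#'
#' @param theta A square numeric matrix.
#' @return `theta` with its diagonal set to exactly 0; off-diagonal entries
#'   are untouched.
#' @examples
#' mask_diagonal(matrix(c(5, 3, 2, 7), 2, 2))
#' @export
mask_diagonal <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) != ncol(theta)) {
    abort(sprintf("`theta` must be square, got %d x %d.", nrow(theta), ncol(theta)))
  }
  diag(theta) <- 0
  theta
}

check_xy_dims <- function(theta, X) {
  if (nrow(theta) != ncol(theta)) {
    abort(sprintf("parameter matrix must be square, got %d x %d.",
                  nrow(theta), ncol(theta)))
  }
  if (ncol(X) != nrow(theta)) {
    abort(sprintf("expression has %d genes but parameter matrix is %d x %d.",
                  ncol(X), nrow(theta), nrow(theta)))
  }
  invisible(TRUE)
}

check_masked <- function(theta, name) {
  if (any(diag(theta) != 0)) {
    abort(sprintf("`%s` must have a zero diagonal; apply mask_diagonal() first.", name))
  }
}

#' Network losses under the unified linear parameterization
#'
#' All three network classes are scored by linear regression residuals, so
#' their mean-squared errors are proportional to the Gaussian negative
#' log-likelihood and directly comparable across estimators of the same
#' class.
#'
#' * `loss_neighborhood()`: each gene is predicted from all others,
#'   \eqn{\|X - X\theta'\|^2} with a zero-diagonal \eqn{\theta'}, plus an
#'   optional lasso penalty on the off-diagonal coefficients.
#' * `loss_markov()`: the regression matrix is constrained symmetric via
#'   \eqn{\theta = \gamma' + \gamma'^T} so that (under a unit-diagonal
#'   precision convention) it coincides with the negated off-diagonal
#'   precision; the penalty applies to \eqn{\gamma'}.
#' * `loss_correlation()`: every ordered gene pair is a separate univariate
#'   regression, \eqn{X_j \approx X_i \theta_{ij}}; the optimum recovers
#'   marginal correlations through \eqn{\hat\rho^2_{ij} = \theta_{ij}\theta_{ji}}.
#'   No sparsity penalty is used for this class.
#'
#' Residual sums are reduced by the mean over all residual terms
#' (`n * p` for neighborhood/Markov, `n * p^2` for correlation) so losses
#' are comparable across sample sizes and gene panels; the penalty is
#' `lambda` times the mean absolute off-diagonal coefficient (sum scaled by
#' `p^2`), keeping the two terms on the same per-entry scale.
#'
#' @param theta,gamma Square `p x p` coefficient matrix. For
#'   `loss_neighborhood()` and `loss_markov()` it must already be
#'   diagonal-masked (see [mask_diagonal()]).
#' @param X Numeric `n x p` expression matrix (samples by genes).
#' @param lambda Nonnegative lasso weight on the mean-scaled objective.
#' @return A single numeric loss value.
#' @seealso [mask_diagonal()], [precision_from_regression()]
#' @examples
#' X <- matrix(c(1, -1, 1, -1), 2, 2)
#' loss_neighborhood(matrix(c(0, 1, 1, 0), 2, 2), X)  # perfect mutual prediction
#' @export
loss_neighborhood <- function(theta, X, lambda = 0) {
  X <- as.matrix(X)
  check_xy_dims(theta, X)
  check_masked(theta, "theta")
  res <- X - X %*% theta
  mean(res^2) + lambda * sum(abs(theta)) / length(theta)
}

#' @rdname loss_neighborhood
#' @export
loss_markov <- function(gamma, X, lambda = 0) {
  X <- as.matrix(X)
  check_xy_dims(gamma, X)
  check_masked(gamma, "gamma")
  theta <- gamma + t(gamma)
  res <- X - X %*% theta
  mean(res^2) + lambda * sum(abs(gamma)) / length(gamma)
}

#' @rdname loss_neighborhood
#' @export
loss_correlation <- function(theta, X) {
  X <- as.matrix(X)
  check_xy_dims(theta, X)
  p <- ncol(X)
  total <- 0
  for (j in seq_len(p)) {
    # predict gene j from each gene i alone with coefficient theta[i, j]
    res <- X[, j] - X * matrix(theta[, j], nrow(X), p, byrow = TRUE)
    total <- total + sum(res^2)
  }
  total / (nrow(X) * p * p)
}

#' Reconstruct a precision matrix from a masked Markov regression matrix
#'
#' Under the unit-diagonal precision convention the symmetric regression
#' matrix equals the negated off-diagonal precision, so
#' \eqn{\hat\Omega = -(\gamma' + \gamma'^T)} with the diagonal filled with 1.
#'
#' @param gamma A zero-diagonal `p x p` regression matrix.
#' @return A symmetric `p x p` precision matrix with unit diagonal.
#' @examples
#' precision_from_regression(matrix(c(0, 0.3, 0.2, 0), 2, 2))
#' @export
precision_from_regression <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != ncol(gamma)) abort("`gamma` must be square.")
  check_masked(gamma, "gamma")
  omega <- -(gamma + t(gamma))
  diag(omega) <- 1
  omega
}

#' Partial correlations from a precision matrix
#'
#' \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}}; the
#' diagonal is set to 1. Zeros of the precision matrix are preserved, so the
#' conditional-independence pattern is unchanged, and the result is
#' invariant to positive rescaling of the precision matrix.
#'
#' @param omega A symmetric precision matrix with strictly positive diagonal.
#' @return The `p x p` matrix of partial correlations.
#' @examples
#' partial_correlation(matrix(c(2, -1, -1, 2), 2, 2))  # rho_12 = 0.5
#' @export
partial_correlation <- function(omega) {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) abort("`omega` must be square.")
  d <- diag(omega)
  if (any(d <= 0)) abort("`omega` must have a strictly positive diagonal.")
  s <- 1 / sqrt(d)
  rho <- -omega * outer(s, s)
  diag(rho) <- 1
  rho
}

#' Reconstruct (squared) correlations from a correlation-network fit
#'
#' The correlation-network coefficients satisfy
#' \eqn{\hat\rho^2_{ij} = \theta_{ij}\theta_{ji}} at the optimum. Gradient
#' training does not constrain the product to `[0, 1]`, so reconstruction
#' optionally clips (with a warning when clipping occurs). The signed form
#' uses \eqn{\mathrm{sign}(\theta_{ij})\sqrt{\max(\theta_{ij}\theta_{ji}, 0)}}.
#'
#' @param theta A square coefficient matrix from a correlation-network fit.
#' @param signed If `TRUE`, return signed correlations; otherwise squared.
#' @param clip If `TRUE` (default) clip squared values into `[0, 1]`.
#' @return A symmetric matrix with unit diagonal.
#' @export
correlation_from_regression <- function(theta, signed = FALSE, clip = TRUE) {
  theta <- as.matrix(theta)
  if (nrow(theta) != ncol(theta)) abort("`theta` must be square.")
  prod <- theta * t(theta)
  if (clip && any(prod > 1 | prod < 0)) {
    warn("squared correlations outside [0, 1] were clipped at reconstruction.")
    prod <- pmin(pmax(prod, 0), 1)
  }
  if (signed) {
    out <- sign(theta) * sqrt(pmax(theta * t(theta), 0))
    out <- (out + t(out)) / 2  # sign pattern is symmetric at any consistent fit
  } else {
    out <- prod
  }
  diag(out) <- 1
  out
}
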