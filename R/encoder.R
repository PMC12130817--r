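# Multilayer-perceptron context encoder and archetype mixing.
#
# The encoder state is a plain list: $W, $b (per-layer weights/biases),
# $hidden (widths), $mode ("linear" or "simplex"), $K. Archetypes are kept
# flattened as a K x p^2 matrix (column-major vec of each p x p matrix) so
# that mixing is a single matrix product: Theta = Z %*% A.

mlp_init <- function(d_in, hidden_widths, K, seed) {
  set.seed(seed)
  widths <- c(d_in, hidden_widths, K)
  W <- list(); b <- list()
  for (l in seq_len(length(widths) - 1)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1]
    W[[l]] <- matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
                     fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b, hidden = hidden_widths, K = K)
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# Forward pass; caches activations for backprop. tanh hidden units keep the
# context-to-weights map smooth, which matters when contexts are continuous.
mlp_forward <- function(enc, C, mode) {
  L <- length(enc$W)
  H <- vector("list", L + 1)
  S <- vector("list", L)
  H[[1]] <- C
  for (l in seq_len(L)) {
    S[[l]] <- sweep(H[[l]] %*% enc$W[[l]], 2, enc$b[[l]], "+")
    H[[l + 1]] <- if (l < L) tanh(S[[l]]) else S[[l]]
  }
  pre <- H[[L + 1]]
  Z <- if (mode == "simplex") softmax_rows(pre) else pre
  list(Z = Z, H = H, S = S, pre = pre)
}

# Backprop given dL/dZ; returns per-layer weight/bias gradients.
mlp_backward <- function(enc, cache, dZ, mode) {
  L <- length(enc$W)
  if (mode == "simplex") {
    Z <- cache$Z
    dZ <- (dZ - rowSums(dZ * Z)) * Z
  }
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dZ
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(enc$W[[l]])) * (1 - tanh(cache$S[[l - 1]])^2)
    }
  }
  list(W = gW, b = gb)
}

#' Mix network archetypes with subtype weights
#'
#' Computes \eqn{\theta = \sum_k Z_k A_k}, the sample-specific parameter
#' matrix as a (convex or linear) combination of the archetype dictionary.
#'
#' @param Z Numeric vector of `K` subtype weights.
#' @param archetypes A list of `K` `p x p` matrices, or a `K x p^2` matrix of
#'   flattened archetypes.
#' @return A `p x p` matrix.
#' @examples
#' A <- list(matrix(c(0, 1, 1, 0), 2), matrix(c(0, -1, -1, 0), 2))
#' mix_archetypes(c(0.5, 0.5), A)  # cancels to zero
#' @export
mix_archetypes <- function(Z, archetypes) {
  if (is.list(archetypes)) {
    p <- nrow(archetypes[[1]])
    A <- t(vapply(archetypes, as.vector, numeric(p * p)))
  } else {
    A <- archetypes
    p <- as.integer(sqrt(ncol(A)))
  }
  if (length(Z) != nrow(A)) {
    abort(sprintf("length(Z) = %d but there are %d archetypes.", length(Z), nrow(A)))
  }
  matrix(as.vector(matrix(Z, 1) %*% A), p, p)
}

# column indices of diagonal entries in the flattened (column-major) layout
diag_cols <- function(p) (seq_len(p) - 1L) * p + seq_len(p)

# permutation sending flattened theta to flattened t(theta)
transpose_perm <- function(p) {
  idx <- matrix(seq_len(p * p), p, p)
  as.vector(t(idx))
}
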