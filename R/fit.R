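# End-to-end training of the context encoder + archetype dictionary.
#
# Parameters are a tree: $A (K x p^2 flattened archetypes) and the encoder
# weights $W / $b. Gradients are hand-derived: the losses are quadratic in
# the per-sample parameter matrix, the mixing step is bilinear, and the MLP
# is standard backprop, so full analytic gradients are cheap and exact.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
}

zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0

adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out <- Map(function(pp, gg, mm, vv) adam_step(pp, gg, mm, vv, lr, t, b1, b2, eps),
               p, g, m, v)
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
}

# Per-sample parameter rows for a batch of encoded contexts (n x p^2),
# masked according to the network class.
theta_rows <- function(enc, A, Cenc, mode, network_class, p) {
  Z <- mlp_forward(enc, Cenc, mode)$Z
  Theta <- Z %*% A
  if (network_class != "correlation") Theta[, diag_cols(p)] <- 0
  Theta
}

# Fit term of the class loss for flattened per-sample parameters (already
# masked); no penalty. Mean over n*p residuals (n*p^2 for correlation).
batch_fit_loss <- function(Theta, X, network_class, p, tperm) {
  n <- nrow(X)
  if (network_class == "correlation") {
    irow <- rep(seq_len(p), times = p)
    jcol <- rep(seq_len(p), each = p)
    R <- X[, jcol, drop = FALSE] - X[, irow, drop = FALSE] * Theta
    return(sum(R^2) / (n * p * p))
  }
  Eff <- if (network_class == "markov") Theta + Theta[, tperm, drop = FALSE] else Theta
  pred <- matrix(0, n, p)
  for (j in seq_len(p)) {
    pred[, j] <- rowSums(X * Eff[, (j - 1L) * p + seq_len(p), drop = FALSE])
  }
  sum((X - pred)^2) / (n * p)
}

# Loss + gradients w.r.t. archetypes and encoder for one batch.
batch_grads <- function(enc, A, Cenc, X, network_class, lambda, mode, p, tperm) {
  n <- nrow(X)
  fw <- mlp_forward(enc, Cenc, mode)
  Theta <- fw$Z %*% A
  dcols <- diag_cols(p)
  if (network_class == "correlation") {
    irow <- rep(seq_len(p), times = p)
    jcol <- rep(seq_len(p), each = p)
    Xi <- X[, irow, drop = FALSE]
    R <- X[, jcol, drop = FALSE] - Xi * Theta
    fit <- sum(R^2) / (n * p * p)
    pen <- 0
    G <- (-2 / (n * p * p)) * Xi * R
  } else {
    Theta[, dcols] <- 0
    Eff <- if (network_class == "markov") Theta + Theta[, tperm, drop = FALSE] else Theta
    pred <- matrix(0, n, p)
    for (j in seq_len(p)) {
      pred[, j] <- rowSums(X * Eff[, (j - 1L) * p + seq_len(p), drop = FALSE])
    }
    res <- X - pred
    fit <- sum(res^2) / (n * p)
    G <- matrix(0, n, p * p)
    for (j in seq_len(p)) {
      G[, (j - 1L) * p + seq_len(p)] <- (-2 / (n * p)) * res[, j] * X
    }
    if (network_class == "markov") G <- G + G[, tperm, drop = FALSE]
    pen <- lambda * sum(abs(Theta)) / (n * p * p)
    G <- G + (lambda / (n * p * p)) * sign(Theta)
    G[, dcols] <- 0
  }
  gA <- crossprod(fw$Z, G)
  dZ <- G %*% t(A)
  genc <- mlp_backward(enc, fw, dZ, mode)
  list(loss = fit + pen, fit = fit,
       grads = list(A = gA, W = genc$W, b = genc$b))
}

coerce_expression <- function(expression) {
  if (is.data.frame(expression)) {
    id_col <- which(vapply(expression, is.character, logical(1)))
    if (length(id_col) && id_col[1] == 1L) {
      ids <- expression[[1]]
      expression <- as.matrix(expression[, -1, drop = FALSE])
      rownames(expression) <- ids
    } else {
      expression <- as.matrix(expression)
    }
  }
  storage.mode(expression) <- "double"
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("g", seq_len(ncol(expression)))
  }
  expression
}

#' Fit a contextualized network model
#'
#' Learns, end to end by gradient descent, a context encoder (a multilayer
#' perceptron) together with a dictionary of `K` network archetypes. Each
#' sample's network parameters are the encoder-weighted mixture of the
#' archetypes, \eqn{\theta_n = \sum_k f(C_n)_k A_k}, scored under the chosen
#' network-class loss. Because parameters are a function of context, the
#' model pools statistical strength across samples and emits a network for
#' any context, including contexts never seen in training.
#'
#' @param expression Numeric matrix or data frame, samples by genes. If
#'   `standardize = TRUE` (default) each gene is z-scored using statistics
#'   from the training split only.
#' @param context Data frame of per-sample metadata (mixed continuous and
#'   categorical), or a numeric matrix. Encoded via [context_schema()]
#'   fitted on the training split.
#' @param network_class One of `"neighborhood"`, `"markov"`,
#'   `"correlation"`.
#' @param K Number of archetypes.
#' @param lambda Lasso weight on off-diagonal coefficients (ignored for the
#'   correlation class, whose loss carries no sparsity term).
#' @param hidden_widths Integer vector of hidden-layer widths; `integer(0)`
#'   gives a linear encoder.
#' @param mode `"linear"` (unconstrained mixing weights, the archetype span)
#'   or `"simplex"` (softmax weights, a convex combination).
#' @param learning_rate,max_epochs,patience,batch_size,val_fraction
#'   Optimization controls: Adam learning rate, epoch cap, early-stopping
#'   patience on the validation loss (computed without the penalty), batch
#'   size (full-batch whenever `n <= batch_size`), and validation fraction
#'   in `[0, 0.5]`.
#' @param standardize Z-score genes with training-split statistics.
#' @param restore_best Return the parameters from the epoch with the best
#'   validation loss (default). With `FALSE` the final-epoch parameters are
#'   returned, which converge to the exact loss optimum in the
#'   homogeneous limit instead of the slightly shrunk best-validation
#'   iterate.
#' @param seed Master seed; the validation split, weight initialization and
#'   epoch shuffling each use a seed derived from it by a fixed counter
#'   scheme, so runs are exactly reproducible.
#' @param verbose Print the loss trace while training.
#' @return An object of class `ctxnet_fit` with the trained encoder,
#'   archetypes, context schema, standardization statistics, loss `trace`
#'   (a tibble with `epoch`, `train_loss`, `val_loss`) and the networks
#'   cached for the training samples.
#' @seealso [predict.ctxnet_fit()], [bootstrap_fit()], [fit_grouped()]
#' @export
contextualized_fit <- function(expression, context,
                               network_class = c("neighborhood", "markov", "correlation"),
                               K = 16, lambda = 1e-3,
                               hidden_widths = c(64, 64),
                               mode = c("linear", "simplex"),
                               learning_rate = 1e-3,
                               max_epochs = 500, patience = 10,
                               batch_size = 1024, val_fraction = 0.2,
                               standardize = TRUE, seed = 1,
                               restore_best = TRUE,
                               verbose = FALSE) {
  network_class <- match.arg(network_class)
  mode <- match.arg(mode)
  X <- coerce_expression(expression)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("need at least 2 samples.")
  if (p < 2) abort("need at least 2 genes.")
  if (val_fraction < 0 || val_fraction > 0.5) abort("`val_fraction` must be in [0, 0.5].")
  if (any(!is.finite(X))) abort("expression contains missing or non-finite values.")
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  if (nrow(context) != n) {
    abort(sprintf("context has %d rows but expression has %d.", nrow(context), n))
  }

  set.seed(derive_seed(seed, 1L))
  n_val <- floor(val_fraction * n)
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  center <- rep(0, p); scale_ <- rep(1, p)
  if (standardize) {
    center <- colMeans(X[train_idx, , drop = FALSE])
    scale_ <- apply(X[train_idx, , drop = FALSE], 2, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }

  schema <- context_schema(context[train_idx, , drop = FALSE])
  Cenc_all <- encode_context(schema, context)
  if (any(!is.finite(Cenc_all))) abort("encoded context contains non-finite values.")
  d <- ncol(Cenc_all)

  enc <- mlp_init(d, hidden_widths, K, derive_seed(seed, 2L))
  set.seed(derive_seed(seed, 3L))
  A <- matrix(rnorm(K * p * p, sd = 1e-2), K, p * p)
  params <- list(A = A, W = enc$W, b = enc$b)
  opt <- list(m = zero_like(params), v = zero_like(params))
  tperm <- transpose_perm(p)

  Xtr <- X[train_idx, , drop = FALSE]
  Ctr <- Cenc_all[train_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]
  Cva <- Cenc_all[val_idx, , drop = FALSE]
  ntr <- length(train_idx)

  eval_fit <- function(params, Cmat, Xmat) {
    enc2 <- enc; enc2$W <- params$W; enc2$b <- params$b
    Th <- theta_rows(enc2, params$A, Cmat, mode, network_class, p)
    batch_fit_loss(Th, Xmat, network_class, p, tperm)
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  trace <- vector("list", max_epochs)
  step_t <- 0L
  stalled <- 0L
  for (epoch in seq_len(max_epochs)) {
    set.seed(derive_seed(seed, 100L + epoch))
    ord <- if (ntr > batch_size) sample.int(ntr) else seq_len(ntr)
    starts <- seq(1L, ntr, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + batch_size - 1L, ntr)]
      enc$W <- params$W; enc$b <- params$b
      bg <- batch_grads(enc, params$A, Ctr[rows, , drop = FALSE],
                        Xtr[rows, , drop = FALSE],
                        network_class, lambda, mode, p, tperm)
      if (!is.finite(bg$loss)) {
        abort(sprintf(
          "non-finite loss at epoch %d (lr = %g); reduce the learning rate or standardize inputs.",
          epoch, learning_rate))
      }
      step_t <- step_t + 1L
      upd <- adam_step(params, bg$grads, opt$m, opt$v, learning_rate, step_t)
      params <- upd$p; opt$m <- upd$m; opt$v <- upd$v
      epoch_loss <- epoch_loss + bg$loss * length(rows)
    }
    train_loss <- epoch_loss / ntr
    val_loss <- if (n_val > 0) eval_fit(params, Cva, Xva) else eval_fit(params, Ctr, Xtr)
    trace[[epoch]] <- c(epoch = epoch, train_loss = train_loss, val_loss = val_loss)
    if (verbose) message(sprintf("epoch %4d  train %.6f  val %.6f", epoch, train_loss, val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) break
    }
  }
  final_val <- if (length(trace) && !is.null(trace[[epoch]])) trace[[epoch]][["val_loss"]] else best$loss
  if (restore_best) params <- best$params
  trace <- tibble::as_tibble(do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))

  fit <- structure(list(
    network_class = network_class,
    K = K, p = p, d = d,
    gene_ids = colnames(X),
    mode = mode,
    hidden_widths = hidden_widths,
    encoder = list(W = params$W, b = params$b, hidden = hidden_widths, K = K),
    archetypes = params$A,
    schema = schema,
    center = center, scale = scale_,
    standardize = standardize,
    lambda = lambda,
    seed = seed,
    trace = trace,
    best_epoch = best$epoch,
    final_train_loss = trace$train_loss[nrow(trace)],
    val_loss = if (restore_best) best$loss else final_val,
    n_train = ntr, n_val = n_val
  ), class = "ctxnet_fit")
  fit$training_networks <- predict(fit, context)
  fit
}

#' @export
print.ctxnet_fit <- function(x, ...) {
  cat(sprintf("<ctxnet_fit> %s network, p = %d genes, K = %d archetypes (%s mixing)\n",
              x$network_class, x$p, x$K, x$mode))
  cat(sprintf("  trained %d epochs (best %d), val loss %.5f, n = %d (+%d val)\n",
              nrow(x$trace), x$best_epoch, x$val_loss, x$n_train, x$n_val))
  invisible(x)
}

#' Predict sample-specific networks from context
#'
#' Emits one parameter matrix per context row. The map is deterministic
#' given the fitted state: identical contexts give identical networks, and
#' contexts never seen in training still receive a network (zero-shot
#' inference).
#'
#' @param object A `ctxnet_fit`.
#' @param context Data frame of contexts matching the fit-time schema.
#' @param ... Unused.
#' @return A `sample_networks` object: an `n x p x p` array with attributes
#'   `network_class` and `gene_ids`. For neighborhood and Markov classes the
#'   per-sample diagonal is exactly zero (for Markov the slices are the
#'   masked pre-symmetrization matrices; see [network_precision()]).
#' @export
predict.ctxnet_fit <- function(object, context, ...) {
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  Cenc <- encode_context(object$schema, context)
  Theta <- theta_rows(object$encoder, object$archetypes, Cenc,
                      object$mode, object$network_class, object$p)
  sample_networks(Theta, object$network_class, object$gene_ids,
                  sample_ids = rownames(context))
}

#' Subtype weights for new contexts
#'
#' Returns the encoder outputs \eqn{Z = f(C)}, the per-sample coordinates in
#' archetype space.
#'
#' @inheritParams predict.ctxnet_fit
#' @param object A `ctxnet_fit`.
#' @return An `n x K` matrix of mixing weights (rows sum to 1 in simplex mode).
#' @export
subtype_weights <- function(object, context) {
  stopifnot(inherits(object, "ctxnet_fit"))
  Cenc <- encode_context(object$schema, as.data.frame(context))
  mlp_forward(object$encoder, Cenc, object$mode)$Z
}

#' Container for per-sample networks
#'
#' @param flat An `n x p^2` matrix of flattened (column-major) parameter
#'   matrices, or an `n x p x p` array.
#' @param network_class Network class tag.
#' @param gene_ids Gene identifiers (length `p`).
#' @param sample_ids Optional sample identifiers.
#' @return An `n x p x p` array of class `sample_networks`.
#' @export
sample_networks <- function(flat, network_class, gene_ids = NULL, sample_ids = NULL) {
  if (length(dim(flat)) == 3) {
    arr <- flat
  } else {
    p <- as.integer(sqrt(ncol(flat)))
    arr <- aperm(array(t(flat), dim = c(p, p, nrow(flat))), c(3, 1, 2))
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(dim(arr)[2]))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(dim(arr)[1]))
  dimnames(arr) <- list(sample_ids, gene_ids, gene_ids)
  structure(arr, network_class = network_class, class = c("sample_networks", "array"))
}

#' @export
print.sample_networks <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sample_networks> %d samples, %d x %d %s networks\n",
              d[1], d[2], d[3], attr(x, "network_class")))
  invisible(x)
}

#' Reconstruct per-sample precision / correlation matrices
#'
#' `network_precision()` maps each Markov-class slice (a masked regression
#' matrix) to its precision matrix \eqn{\hat\Omega = -(\gamma' + \gamma'^T)}
#' with unit diagonal. `network_correlation()` maps correlation-class slices
#' to (squared or signed) Pearson correlation estimates.
#'
#' @param networks A `sample_networks` object.
#' @param signed For `network_correlation()`, return signed correlations.
#' @return A `sample_networks` array tagged `"precision"` or `"correlation"`.
#' @export
network_precision <- function(networks) {
  stopifnot(inherits(networks, "sample_networks"))
  if (attr(networks, "network_class") != "markov") {
    abort("precision reconstruction is defined for Markov-class networks.")
  }
  out <- networks
  for (i in seq_len(dim(networks)[1])) {
    out[i, , ] <- precision_from_regression(networks[i, , ])
  }
  attr(out, "network_class") <- "precision"
  out
}

#' @rdname network_precision
#' @export
network_correlation <- function(networks, signed = FALSE) {
  stopifnot(inherits(networks, "sample_networks"))
  if (attr(networks, "network_class") != "correlation") {
    abort("correlation reconstruction is defined for correlation-class networks.")
  }
  out <- networks
  clipped <- FALSE
  for (i in seq_len(dim(networks)[1])) {
    out[i, , ] <- withCallingHandlers(
      correlation_from_regression(networks[i, , ], signed = signed),
      warning = function(w) { clipped <<- TRUE; invokeRestart("muffleWarning") })
  }
  if (clipped) warn("some squared correlations were clipped into [0, 1].")
  attr(out, "network_class") <- if (signed) "correlation_signed" else "correlation_squared"
  out
}

#' Bootstrap ensemble of contextualized network models
#'
#' Fits `B` models on with-replacement resamples of the training rows, each
#' with its own derived seed and fresh random initialization. Ensemble
#' predictions are the entrywise mean of the member networks, with the
#' across-member standard deviation reported as a spread estimate. With
#' `B = 1` no resampling is done, so the ensemble is exactly the single fit.
#'
#' @inheritParams contextualized_fit
#' @param B Number of bootstrap members.
#' @param ... Passed to [contextualized_fit()].
#' @return A `ctxnet_ensemble` (list of member fits).
#' @export
bootstrap_fit <- function(expression, context, B = 30, seed = 1, ...) {
  stopifnot(B >= 1)
  X <- coerce_expression(expression)
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  n <- nrow(X)
  members <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    rows <- if (B == 1) seq_len(n) else {
      set.seed(derive_seed(seed, 500L + b))
      sample.int(n, n, replace = TRUE)
    }
    members[[b]] <- tryCatch(
      contextualized_fit(X[rows, , drop = FALSE], context[rows, , drop = FALSE],
                         seed = seed + b - 1L, ...),
      error = function(e) {
        warn(sprintf("bootstrap member %d failed: %s", b, conditionMessage(e)))
        NULL
      })
    if (is.null(members[[b]])) failed <- failed + 1L
  }
  ok <- !vapply(members, is.null, logical(1))
  if (sum(ok) < max(1, floor(B / 2))) {
    abort(sprintf("only %d of %d bootstrap members succeeded.", sum(ok), B))
  }
  structure(list(members = members[ok], B = B, seed = seed),
            class = "ctxnet_ensemble")
}

#' @export
print.ctxnet_ensemble <- function(x, ...) {
  cat(sprintf("<ctxnet_ensemble> %d member fits (%s networks)\n",
              length(x$members), x$members[[1]]$network_class))
  invisible(x)
}

#' @describeIn bootstrap_fit Ensemble prediction: entrywise mean across
#'   members, with the SD across members attached as attribute `"sd"`.
#' @param object A `ctxnet_ensemble`.
#' @export
predict.ctxnet_ensemble <- function(object, context, ...) {
  preds <- lapply(object$members, predict, context = context)
  mean_arr <- Reduce(`+`, lapply(preds, unclass)) / length(preds)
  sq <- Reduce(`+`, lapply(preds, function(a) unclass(a)^2)) / length(preds)
  sd_arr <- sqrt(pmax(sq - mean_arr^2, 0))
  out <- sample_networks(mean_arr, attr(preds[[1]], "network_class"),
                         gene_ids = dimnames(preds[[1]])[[2]])
  attr(out, "sd") <- sd_arr
  out
}
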