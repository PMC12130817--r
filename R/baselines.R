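# Population / cohort / context-clustered baseline estimators, fitted under
# the same class losses as the contextualized model so that expression-MSE
# comparisons are like for like.

# Closed-form single-network fits for lambda = 0; Adam otherwise.
fit_single_network <- function(X, network_class, lambda = 0,
                               learning_rate = 0.05, max_iter = 2000, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  if (n < p && network_class != "correlation") {
    warn(sprintf("degenerate fit: %d sample(s) for %d genes (n < p).", n, p))
  }
  if (lambda == 0) {
    if (network_class == "neighborhood") {
      theta <- matrix(0, p, p)
      for (j in seq_len(p)) {
        co <- qr.coef(qr(X[, -j, drop = FALSE]), X[, j])
        co[is.na(co)] <- 0
        theta[-j, j] <- co
      }
      return(theta)
    }
    if (network_class == "correlation") {
      S <- crossprod(X)
      denom <- diag(S)
      theta <- S / ifelse(denom == 0, Inf, denom)  # theta[i, j] = <Xi,Xj>/<Xi,Xi>
      diag(theta) <- ifelse(denom == 0, 0, 1)
      return(theta)
    }
    # markov: quadratic in the p(p-1)/2 free entries of the symmetric
    # zero-diagonal regression matrix; solve the least-squares system exactly
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    m <- nrow(pairs)
    D <- matrix(0, n * p, m)
    for (k in seq_len(m)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      Ek <- matrix(0, n, p)
      Ek[, j] <- X[, i]
      Ek[, i] <- X[, j]
      D[, k] <- as.vector(Ek)
    }
    t_hat <- qr.coef(qr(D), as.vector(X))
    t_hat[is.na(t_hat)] <- 0
    gamma <- matrix(0, p, p)
    # return the half-weight pre-symmetrization matrix so gamma + t(gamma)
    # reproduces the symmetric solution
    gamma[pairs] <- t_hat / 2
    gamma[pairs[, c(2, 1), drop = FALSE]] <- t_hat / 2
    return(gamma)
  }
  # subgradient Adam on a single shared parameter matrix
  theta <- matrix(0, p, p)
  mconst <- 0 * theta; vconst <- mconst
  s_diag <- NULL
  if (network_class == "correlation") {
    S <- crossprod(X); s_diag <- diag(S)
  }
  prev <- Inf
  for (it in seq_len(max_iter)) {
    if (network_class == "neighborhood") {
      th <- mask_diagonal(theta)
      res <- X - X %*% th
      g <- -2 / (n * p) * crossprod(X, res) + lambda / (p * p) * sign(th)
      g <- mask_diagonal(g)
      loss <- mean(res^2) + lambda * sum(abs(th)) / (p * p)
    } else if (network_class == "markov") {
      gm <- mask_diagonal(theta)
      res <- X - X %*% (gm + t(gm))
      G <- -2 / (n * p) * crossprod(X, res)
      g <- mask_diagonal(G + t(G) + lambda / (p * p) * sign(gm))
      loss <- mean(res^2) + lambda * sum(abs(gm)) / (p * p)
    } else {
      g <- -2 / (n * p * p) * (S - theta * s_diag)
      res_loss <- sum(vapply(seq_len(p), function(j) {
        sum((X[, j] - X * matrix(theta[, j], n, p, byrow = TRUE))^2)
      }, numeric(1)))
      loss <- res_loss / (n * p * p)
    }
    upd <- adam_step(theta, g, mconst, vconst, learning_rate, it)
    theta <- upd$p; mconst <- upd$m; vconst <- upd$v
    if (abs(prev - loss) < tol) break
    prev <- loss
  }
  if (network_class != "correlation") theta <- mask_diagonal(theta)
  theta
}

#' Fit population, cohort, or context-clustered baseline networks
#'
#' The three classical alternatives to sample-specific estimation:
#' a single network for everyone (`"population"`), one network per known
#' group label such as disease type (`"labels"`), or one network per
#' k-means cluster of the encoded context (`"context_clusters"`). Each
#' group's network minimizes the same class loss as the contextualized
#' model, restricted to that group's samples (closed-form least squares
#' when `lambda = 0`).
#'
#' @param expression Samples-by-genes matrix or data frame.
#' @param context Data frame of contexts; required for
#'   `scheme = "context_clusters"`.
#' @param scheme Grouping scheme.
#' @param labels Group label per sample (required for `scheme = "labels"`).
#' @param n_clusters Number of context clusters; if `NULL`, chosen by the
#'   best mean silhouette over k = 2..10.
#' @param network_class,lambda As in [contextualized_fit()].
#' @param standardize Z-score genes with whole-training-set statistics.
#' @param seed Seed for k-means initialization.
#' @return A `grouped_fit`: per-group parameter matrices plus the metadata
#'   needed to route new samples to a group.
#' @export
fit_grouped <- function(expression, context = NULL,
                        scheme = c("population", "labels", "context_clusters"),
                        labels = NULL, n_clusters = NULL,
                        network_class = c("neighborhood", "markov", "correlation"),
                        lambda = 0, standardize = TRUE, seed = 1) {
  scheme <- match.arg(scheme)
  network_class <- match.arg(network_class)
  X <- coerce_expression(expression)
  n <- nrow(X); p <- ncol(X)
  center <- rep(0, p); scale_ <- rep(1, p)
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  schema <- NULL; centers <- NULL
  if (scheme == "population") {
    groups <- rep("population", n)
  } else if (scheme == "labels") {
    if (is.null(labels)) abort("`labels` is required for scheme = 'labels'.")
    if (length(labels) != n) abort("`labels` length must match the sample count.")
    groups <- as.character(labels)
  } else {
    if (is.null(context)) abort("`context` is required for scheme = 'context_clusters'.")
    context <- as.data.frame(context, stringsAsFactors = FALSE)
    schema <- context_schema(context)
    Cenc <- encode_context(schema, context)
    if (is.null(n_clusters)) {
      n_clusters <- select_k_silhouette(Cenc, k_range = 2:min(10, n - 1))
    }
    set.seed(derive_seed(seed, 7L))
    km <- kmeans(Cenc, centers = n_clusters, nstart = 10)
    centers <- km$centers
    groups <- as.character(km$cluster)
  }
  nets <- lapply(split(seq_len(n), groups), function(rows) {
    fit_single_network(X[rows, , drop = FALSE], network_class, lambda)
  })
  structure(list(
    scheme = scheme, network_class = network_class,
    networks = nets, group_sizes = table(groups),
    labels = if (scheme == "labels") groups else NULL,
    schema = schema, centers = centers,
    center = center, scale = scale_, standardize = standardize,
    gene_ids = colnames(X), p = p, lambda = lambda
  ), class = "grouped_fit")
}

#' @export
print.grouped_fit <- function(x, ...) {
  cat(sprintf("<grouped_fit> scheme '%s', %d group(s), %s networks, p = %d\n",
              x$scheme, length(x$networks), x$network_class, x$p))
  invisible(x)
}

#' Predict baseline networks for samples
#'
#' Routes each sample to its group's network: everyone gets the single
#' network under the population scheme; `labels` mode requires each label to
#' have been seen in training (an unseen label is an error — cohort modeling
#' cannot be applied to an entirely new cohort); `context_clusters` mode
#' assigns the nearest k-means centroid in encoded context space.
#'
#' @param object A `grouped_fit`.
#' @param context Contexts (for `context_clusters`).
#' @param labels Labels (for `labels`).
#' @param n Number of samples (for `population`, when neither `context` nor
#'   `labels` is given).
#' @param ... Unused.
#' @return A `sample_networks` array.
#' @export
predict.grouped_fit <- function(object, context = NULL, labels = NULL, n = NULL, ...) {
  if (object$scheme == "population") {
    if (is.null(n)) {
      n <- if (!is.null(labels)) length(labels)
      else if (!is.null(context)) nrow(as.data.frame(context))
      else abort("give `n` (or `context`/`labels`) to size the prediction.")
    }
    idx <- rep("population", n)
  } else if (object$scheme == "labels") {
    if (is.null(labels)) abort("`labels` is required for a cohort fit.")
    idx <- as.character(labels)
    unseen <- setdiff(unique(idx), names(object$networks))
    if (length(unseen)) {
      abort(paste0("cohort model has no network for unseen label(s): ",
                   paste(unseen, collapse = ", "),
                   ". Cohort-specific inference cannot be applied to new groups."))
    }
  } else {
    if (is.null(context)) abort("`context` is required for a context-cluster fit.")
    Cenc <- encode_context(object$schema, as.data.frame(context))
    d2 <- outer(rowSums(Cenc^2), rowSums(object$centers^2), "+") -
      2 * Cenc %*% t(object$centers)
    idx <- rownames(object$centers)[max.col(-d2)]
  }
  p <- object$p
  flat <- t(vapply(idx, function(g) as.vector(object$networks[[g]]), numeric(p * p)))
  sample_networks(flat, object$network_class, object$gene_ids)
}
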