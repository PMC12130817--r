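# Context-varying Gaussian benchmark: C ~ Unif[-1, 1] and
# X ~ N(0, [[1, C], [C, 1]]), the minimal setting where the network truly
# changes with context and ground-truth precision matrices are available in
# closed form.

#' Specify a context-varying Gaussian simulation
#'
#' @param n_contexts Number of distinct contexts (experimental conditions).
#' @param samples_per_context i.i.d. draws per context (replicates).
#' @param context_range Support of the uniform context law.
#' @param context_eps Guard keeping `|C| <= 1 - context_eps` so the 2x2
#'   covariance stays well conditioned.
#' @param seed RNG seed.
#' @return A `cvg_spec` list.
#' @export
cvg_spec <- function(n_contexts = 100, samples_per_context = 1,
                     context_range = c(-1, 1), context_eps = 0.01, seed = 1) {
  stopifnot(n_contexts >= 1, samples_per_context >= 1, context_eps > 0)
  structure(list(n_contexts = n_contexts,
                 samples_per_context = samples_per_context,
                 context_range = context_range,
                 context_eps = context_eps, seed = seed),
            class = "cvg_spec")
}

#' Draw a dataset from the context-varying Gaussian
#'
#' @param spec A [cvg_spec()].
#' @return A list with `data` (a tibble: `sample_id`, `context`, `g1`,
#'   `g2`), `context` (an `n x 1` data frame), `expression` (an `n x 2`
#'   matrix) and `true_precision` (an `n x 2 x 2` array of ground-truth
#'   precision matrices).
#' @export
sample_cvg <- function(spec) {
  stopifnot(inherits(spec, "cvg_spec"))
  set.seed(spec$seed)
  lo <- spec$context_range[1]; hi <- spec$context_range[2]
  eps <- spec$context_eps
  C <- runif(spec$n_contexts, max(lo, -1 + eps), min(hi, 1 - eps))
  C <- rep(C, each = spec$samples_per_context)
  n <- length(C)
  z1 <- rnorm(n); z2 <- rnorm(n)
  # X ~ N(0, [[1, C], [C, 1]]) via the Cholesky factor of each 2x2 covariance
  x1 <- z1
  x2 <- C * z1 + sqrt(1 - C^2) * z2
  X <- cbind(g1 = x1, g2 = x2)
  truth <- array(0, dim = c(n, 2, 2))
  for (i in seq_len(n)) truth[i, , ] <- true_precision(C[i])
  list(
    data = tibble::tibble(sample_id = as.character(seq_len(n)),
                          context = C, g1 = x1, g2 = x2),
    context = data.frame(context = C),
    expression = X,
    true_precision = sample_networks(truth, "precision", gene_ids = c("g1", "g2"))
  )
}

#' Ground-truth precision matrix of the 2-gene simulation
#'
#' Inverse of `[[1, C], [C, 1]]`:
#' \eqn{\Omega(C) = (1 - C^2)^{-1} [[1, -C], [-C, 1]]}.
#'
#' @param C Context value with `|C| < 1`.
#' @return A 2x2 precision matrix.
#' @export
true_precision <- function(C) {
  if (abs(C) >= 1) abort("|C| must be < 1 for a positive-definite covariance.")
  matrix(c(1, -C, -C, 1), 2, 2) / (1 - C^2)
}

unit_diag_scale <- function(M) {
  s <- 1 / sqrt(diag(M))
  M * outer(s, s)
}

#' Mean squared error between per-sample parameter estimates and truth
#'
#' By default both sides are rescaled to unit diagonal first (so the metric
#' compares partial-correlation-scaled precisions and is independent of the
#' diagonal convention of either estimator); set `normalize = FALSE` to
#' compare raw entries.
#'
#' @param estimated,truth `n x p x p` arrays (e.g. `sample_networks`).
#' @param normalize Rescale each matrix to unit diagonal before comparing.
#' @return Mean over all samples and all `p^2` entries of squared
#'   differences.
#' @export
parameter_mse <- function(estimated, truth, normalize = TRUE) {
  estimated <- unclass(estimated); truth <- unclass(truth)
  if (!identical(dim(estimated), dim(truth))) {
    abort("`estimated` and `truth` must have identical dimensions.")
  }
  n <- dim(truth)[1]
  total <- 0
  for (i in seq_len(n)) {
    E <- estimated[i, , ]; Tr <- truth[i, , ]
    if (normalize) { E <- unit_diag_scale(E); Tr <- unit_diag_scale(Tr) }
    total <- total + mean((E - Tr)^2)
  }
  total / n
}

# Fit one estimator on a simulated cell and return per-sample precision
# estimates on the same rows.
estimate_cell <- function(dat, estimator, network_class = "markov",
                          seed = 1, fit_args = list()) {
  n <- nrow(dat$expression)
  if (estimator == "population") {
    g <- fit_grouped(dat$expression, scheme = "population",
                     network_class = network_class, lambda = 0)
    nets <- predict(g, n = n)
  } else if (estimator == "grouped") {
    labs <- as.character(match(dat$context$context, unique(dat$context$context)))
    g <- suppressWarnings(
      fit_grouped(dat$expression, scheme = "labels", labels = labs,
                  network_class = network_class, lambda = 0))
    nets <- predict(g, labels = labs)
  } else if (estimator == "contextualized") {
    args <- utils::modifyList(list(
      expression = dat$expression, context = dat$context,
      network_class = network_class, K = 4, lambda = 0,
      hidden_widths = c(16, 16), learning_rate = 5e-3,
      max_epochs = 300, patience = 20, seed = seed), fit_args)
    fit <- do.call(contextualized_fit, args)
    nets <- predict(fit, dat$context)
  } else {
    abort(sprintf("unknown estimator '%s'.", estimator))
  }
  if (network_class == "markov") network_precision(nets) else nets
}

#' Horizontal-vs-vertical scaling benchmark grid
#'
#' Sweeps the number of contexts (horizontal scaling: more distinct
#' experimental conditions) against samples per context (vertical scaling:
#' more replicates per condition) and scores each estimator by
#' [parameter_mse()] against the ground-truth precision matrices, averaged
#' over replicate draws.
#'
#' @param n_contexts,samples_per_context Integer vectors defining the grid.
#' @param estimators Subset of `"population"`, `"grouped"`,
#'   `"contextualized"`.
#' @param replicates Replicate simulation draws per cell.
#' @param network_class Network class scored (the benchmark's ground truth
#'   is a precision matrix, so `"markov"` is the natural choice).
#' @param seed Master seed; each (cell, replicate) derives its own.
#' @param fit_args Overrides for the contextualized fit in each cell.
#' @return A tibble of class `scaling_grid`: `estimator`, `n_contexts`,
#'   `samples_per_context`, `replicate`, `parameter_mse` (NA if a cell
#'   failed).
#' @export
run_scaling_grid <- function(n_contexts = c(1, 10, 100, 1000),
                             samples_per_context = c(1, 10, 100),
                             estimators = c("population", "grouped", "contextualized"),
                             replicates = 5,
                             network_class = "markov",
                             seed = 1, fit_args = list()) {
  cells <- expand.grid(n_contexts = n_contexts,
                       samples_per_context = samples_per_context,
                       replicate = seq_len(replicates))
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    nc <- cells$n_contexts[r]; spc <- cells$samples_per_context[r]
    rep_i <- cells$replicate[r]
    cell_seed <- derive_seed(seed, r)
    dat <- sample_cvg(cvg_spec(nc, spc, seed = cell_seed))
    purrr::map_dfr(estimators, function(est) {
      mse <- tryCatch(
        parameter_mse(
          suppressWarnings(estimate_cell(dat, est, network_class, seed = cell_seed)),
          dat$true_precision),
        error = function(e) NA_real_)
      tibble::tibble(estimator = est, n_contexts = nc,
                     samples_per_context = spc, replicate = rep_i,
                     parameter_mse = mse)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scaling_grid", class(out))
  out
}
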