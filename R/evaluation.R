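# Expression-MSE scoring of per-sample network sets, relative MSE against a
# named baseline, and the hold-out-group cross-validation harness.

#' Per-sample expression mean squared error
#'
#' Scores how well each sample's network predicts that sample's expression
#' under the class's linear predictive form: `X - X theta` per gene for
#' neighborhood, the symmetrized `X - X (gamma + gamma^T)` for Markov, and
#' per-ordered-pair univariate residuals for correlation. No sparsity
#' penalty enters the score, and because residuals are Gaussian
#' log-likelihood terms, smaller MSE means higher likelihood.
#'
#' @param networks A `sample_networks` object, row-aligned with `X`.
#' @param X Expression matrix on the same scale the networks were fitted on
#'   (see [standardize_like()]).
#' @return Numeric vector of per-sample MSEs (length `n`).
#' @export
expression_mse <- function(networks, X) {
  stopifnot(inherits(networks, "sample_networks"))
  X <- as.matrix(X)
  cls <- attr(networks, "network_class")
  n <- dim(networks)[1]; p <- dim(networks)[2]
  if (nrow(X) != n || ncol(X) != p) {
    abort(sprintf("X is %d x %d but networks are %d samples of %d genes.",
                  nrow(X), ncol(X), n, p))
  }
  if (!cls %in% c("neighborhood", "markov", "correlation")) {
    abort(sprintf("expression MSE is undefined for network class '%s'.", cls))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    th <- networks[i, , ]
    x <- X[i, ]
    if (cls == "correlation") {
      res <- outer(x, rep(1, p)) * th  # res[i, j] = x_i * theta_ij
      out[i] <- mean((matrix(x, p, p, byrow = TRUE) - res)^2)
    } else {
      eff <- if (cls == "markov") th + t(th) else th
      out[i] <- mean((x - as.vector(x %*% eff))^2)
    }
  }
  out
}

#' Re-apply a fit's gene standardization to new expression
#'
#' @param fit A `ctxnet_fit` or `grouped_fit`.
#' @param X Raw expression, samples by genes.
#' @return `X` z-scored with the statistics frozen at fit time.
#' @export
standardize_like <- function(fit, X) {
  X <- coerce_expression(X)
  if (!isTRUE(fit$standardize)) return(X)
  sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
}

#' Tidy evaluation report for a set of per-sample networks
#'
#' @param networks A `sample_networks` object.
#' @param X Expression matrix aligned with `networks`.
#' @param groups Optional group label per sample (e.g. disease type).
#' @param model Name recorded in the `model` column.
#' @return A tibble: `sample_id`, `model`, `group`, `mse`.
#' @seealso [relative_mse()], [holdout_group_cv()]
#' @export
evaluation_report <- function(networks, X, groups = NULL, model = "model") {
  mse <- expression_mse(networks, X)
  tibble::tibble(
    sample_id = dimnames(networks)[[1]],
    model = model,
    group = if (is.null(groups)) "all" else as.character(groups),
    mse = mse)
}

#' Group-wise relative MSE against a baseline report
#'
#' Ratios of group-mean MSEs, baseline in the denominator, so the baseline
#' scores exactly 1 against itself and values below 1 are improvements. A
#' zero baseline mean is flagged as undefined (`NA`) rather than infinity.
#'
#' @param report,baseline_report Tibbles from [evaluation_report()], with
#'   the same groups.
#' @return A tibble: `group`, `model`, `mse`, `baseline_mse`,
#'   `relative_mse`, `undefined`.
#' @export
relative_mse <- function(report, baseline_report) {
  num <- dplyr::summarise(dplyr::group_by(report, .data$group, .data$model),
                          mse = mean(.data$mse), .groups = "drop")
  den <- dplyr::summarise(dplyr::group_by(baseline_report, .data$group),
                          baseline_mse = mean(.data$mse), .groups = "drop")
  out <- dplyr::left_join(num, den, by = "group")
  if (anyNA(out$baseline_mse)) {
    abort("baseline report is missing some groups present in `report`.")
  }
  out$undefined <- out$baseline_mse == 0
  if (any(out$undefined)) warn("zero baseline MSE in some group(s); relative MSE set to NA there.")
  out$relative_mse <- ifelse(out$undefined, NA_real_, out$mse / out$baseline_mse)
  out
}

#' Hold-out-group cross-validation
#'
#' The generalization protocol for entirely new cohorts: each group (e.g. a
#' disease type) is excluded from training in turn, models are fitted on
#' the remaining samples, and the held-out group is scored at test time.
#' The cohort ("labels") baseline has no network for a group it never saw,
#' so it is reported as not applicable there — only context-driven models
#' can make this prediction.
#'
#' @param expression Samples-by-genes matrix.
#' @param context Context data frame.
#' @param groups Group label per sample.
#' @param network_class,lambda As in [contextualized_fit()].
#' @param fit_args List of overrides passed to [contextualized_fit()].
#' @param models Which models to evaluate: any of `"contextualized"`,
#'   `"population"`, `"labels"`.
#' @param seed Master seed.
#' @return A tibble: `group`, `model`, `n`, `mse`, `applicable` (`FALSE`
#'   with `mse = NA` where a model cannot be applied to the held-out
#'   group).
#' @export
holdout_group_cv <- function(expression, context, groups,
                             network_class = "neighborhood", lambda = 0,
                             fit_args = list(),
                             models = c("contextualized", "population", "labels"),
                             seed = 1) {
  X <- coerce_expression(expression)
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) abort("need at least 2 groups to hold out.")
  rows <- lapply(gl, function(g) {
    test <- groups == g
    if (sum(test) == 1) warn(sprintf("group '%s' is a singleton; evaluated anyway.", g))
    Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    Ctr <- context[!test, , drop = FALSE]; Cte <- context[test, , drop = FALSE]
    out <- list()
    if ("contextualized" %in% models) {
      args <- utils::modifyList(list(
        expression = Xtr, context = Ctr, network_class = network_class,
        lambda = lambda, seed = seed), fit_args)
      fit <- do.call(contextualized_fit, args)
      nets <- predict(fit, Cte)
      out$contextualized <- mean(expression_mse(nets, standardize_like(fit, Xte)))
    }
    if ("population" %in% models) {
      pop <- fit_grouped(Xtr, scheme = "population",
                         network_class = network_class, lambda = lambda)
      nets <- predict(pop, n = sum(test))
      out$population <- mean(expression_mse(nets, standardize_like(pop, Xte)))
    }
    res <- tibble::tibble(group = g,
                          model = names(out),
                          n = sum(test),
                          mse = unlist(out, use.names = FALSE),
                          applicable = TRUE)
    if ("labels" %in% models) {
      # the cohort baseline never saw this group: structurally inapplicable
      res <- dplyr::bind_rows(res, tibble::tibble(
        group = g, model = "labels", n = sum(test),
        mse = NA_real_, applicable = FALSE))
    }
    res
  })
  dplyr::bind_rows(rows)
}
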