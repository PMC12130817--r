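# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @method tidy sample_networks
#' @export
tidy.sample_networks <- function(x, ...) {
  cls <- attr(x, "network_class")
  n <- dim(x)[1]; p <- dim(x)[2]
  genes <- dimnames(x)[[2]]
  samples <- dimnames(x)[[1]]
  grid <- expand.grid(i = seq_len(p), j = seq_len(p))
  if (cls %in% c("neighborhood", "markov")) grid <- grid[grid$i != grid$j, ]
  rows <- lapply(seq_len(n), function(s) {
    tibble::tibble(sample_id = samples[s],
                   gene_i = genes[grid$i], gene_j = genes[grid$j],
                   value = x[s, , ][cbind(grid$i, grid$j)],
                   network_class = cls)
  })
  dplyr::bind_rows(rows)
}

#' @method tidy ctxnet_fit
#' @export
tidy.ctxnet_fit <- function(x, ...) {
  x$trace
}

#' @method glance ctxnet_fit
#' @export
glance.ctxnet_fit <- function(x, ...) {
  tibble::tibble(network_class = x$network_class, p = x$p, K = x$K,
                 mode = x$mode, lambda = x$lambda,
                 n_train = x$n_train, n_val = x$n_val,
                 epochs = nrow(x$trace), best_epoch = x$best_epoch,
                 train_loss = x$final_train_loss, val_loss = x$val_loss)
}

#' @method tidy subtype_report
#' @export
tidy.subtype_report <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels) %||% as.character(seq_along(x$labels)),
                 subtype = unname(x$labels))
}

#' @method glance subtype_report
#' @export
glance.subtype_report <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_silhouette = x$clustering$silhouette,
    logrank_chisq = if (!is.null(x$logrank)) x$logrank$chisq else NA_real_,
    logrank_p = if (!is.null(x$logrank)) x$logrank$multivariate_p else NA_real_,
    min_pairwise_logrank_p = if (!is.null(x$logrank)) x$logrank$min_pairwise_p else NA_real_,
    top_feature = if (!is.null(x$feature_pvalues)) x$feature_pvalues$feature[1] else NA_character_,
    top_feature_p = if (!is.null(x$feature_pvalues)) x$feature_pvalues$p_value[1] else NA_real_)
}

#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$multivariate_p,
                 min_pairwise_p = x$min_pairwise_p,
                 neg_log10_p = x$neg_log10_multivariate,
                 neg_log10_min_pairwise = x$neg_log10_min_pairwise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method autoplot ctxnet_fit
#' @export
autoplot.ctxnet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = sprintf("%s network training", object$network_class)) +
    ggplot2::theme_minimal()
}

#' @method autoplot sample_networks
#' @export
autoplot.sample_networks <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::summarise(dplyr::group_by(df, .data$gene_i, .data$gene_j),
                         value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_j, y = .data$gene_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = sprintf("mean %s network", attr(object, "network_class")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot scaling_grid
#' @export
autoplot.scaling_grid <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object, .data$estimator, .data$n_contexts,
                    .data$samples_per_context),
    parameter_mse = mean(.data$parameter_mse, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_contexts),
                                   y = factor(.data$samples_per_context),
                                   fill = log10(.data$parameter_mse))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "contexts (horizontal scaling)",
                  y = "samples per context (vertical scaling)",
                  fill = "log10 MSE") +
    ggplot2::theme_minimal()
}

#' @method autoplot subtype_report
#' @export
autoplot.subtype_report <- function(object, ...) {
  tab <- object$clustering$silhouette_by_k
  if (is.null(tab)) {
    tab <- tibble::tibble(k = object$k, silhouette = object$clustering$silhouette)
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}
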