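# Network-parameter subtype discovery: Ward clustering of flattened
# per-sample networks, silhouette-based model selection, context-feature
# association by subtype-vs-rest t-tests, and log-rank survival tests.

#' Flatten per-sample networks for clustering
#'
#' Neighborhood networks are asymmetric, so all off-diagonal entries are
#' kept; Markov networks are first reconstructed to their symmetric
#' precision form and correlation networks to signed correlations, and only
#' the upper triangle is kept, so symmetric entries are not double-weighted.
#'
#' @param networks A `sample_networks` object.
#' @return An `n x q` numeric matrix of per-sample feature vectors.
#' @export
flatten_networks <- function(networks) {
  stopifnot(inherits(networks, "sample_networks"))
  cls <- attr(networks, "network_class")
  n <- dim(networks)[1]; p <- dim(networks)[2]
  if (cls == "markov") networks <- network_precision(networks)
  if (cls == "correlation") networks <- suppressWarnings(network_correlation(networks, signed = TRUE))
  keep <- if (cls == "neighborhood") {
    which(row(diag(p)) != col(diag(p)))
  } else {
    which(upper.tri(diag(p)))
  }
  vals <- vapply(seq_len(n), function(i) as.vector(networks[i, , ])[keep],
                 numeric(length(keep)))
  out <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
  rownames(out) <- dimnames(networks)[[1]]
  out
}

#' Ward clustering of sample-specific networks
#'
#' Hierarchical clustering with Ward linkage on the Euclidean distance
#' between flattened network parameters; the dendrogram is cut at `k`
#' clusters. Deterministic and invariant (up to label names) to sample
#' order.
#'
#' @param networks A `sample_networks` object, or an already-flattened
#'   numeric matrix.
#' @param k Number of clusters, or `"auto"` to select by silhouette
#'   (see [select_k_silhouette()]).
#' @param k_range Candidate k values used when `k = "auto"`.
#' @return A list of class `network_clustering`: `labels` (integer vector),
#'   `k`, `silhouette` (mean silhouette at the chosen k),
#'   `silhouette_by_k` (tibble, present when `k = "auto"`), `hclust`.
#' @export
cluster_networks <- function(networks, k = "auto", k_range = 2:10) {
  flat <- if (inherits(networks, "sample_networks")) flatten_networks(networks) else as.matrix(networks)
  n <- nrow(flat)
  sil_tab <- NULL
  if (identical(k, "auto")) {
    sel <- select_k_silhouette(flat, k_range = k_range, details = TRUE)
    k <- sel$k
    sil_tab <- sel$table
  }
  k <- as.integer(k)
  if (k > n) abort(sprintf("k = %d exceeds the sample count %d.", k, n))
  hc <- hclust(dist(flat), method = "ward.D2")
  labels <- cutree(hc, k = k)
  d <- dist(flat)
  if (!any(d > 0)) {
    warn("all networks identical: the requested split is degenerate (one effective cluster).")
  }
  sil <- if (k >= 2 && k < n && any(d > 0)) {
    mean(cluster::silhouette(labels, d)[, 3])
  } else NA_real_
  if (!is.na(sil) && sil <= 0) {
    warn(sprintf("degenerate split: mean silhouette %.3f <= 0 at k = %d.", sil, k))
  }
  structure(list(labels = labels, k = k, silhouette = sil,
                 silhouette_by_k = sil_tab, hclust = hc),
            class = "network_clustering")
}

#' Select the number of clusters by silhouette
#'
#' Cuts the Ward dendrogram at each candidate k and keeps the k with the
#' best mean silhouette width; ties go to the smallest k. If every
#' pairwise distance is zero the silhouette is undefined and the selection
#' falls back to the smallest candidate with a warning.
#'
#' @param x A `sample_networks` object or numeric matrix of per-sample
#'   feature vectors.
#' @param k_range Candidate cluster counts (default 2..10).
#' @param details Return the full silhouette trace as well.
#' @return The selected k (integer), or a list with `k` and `table` when
#'   `details = TRUE`.
#' @export
select_k_silhouette <- function(x, k_range = 2:10, details = FALSE) {
  flat <- if (inherits(x, "sample_networks")) flatten_networks(x) else as.matrix(x)
  n <- nrow(flat)
  if (n <= 2) abort("need more than 2 samples to select k.")
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) abort("no admissible k in `k_range`.")
  d <- dist(flat)
  if (all(d == 0)) {
    warn("all samples identical: silhouette undefined, falling back to the smallest k.")
    k <- min(k_range)
    tab <- tibble::tibble(k = k_range, silhouette = NA_real_)
    return(if (details) list(k = k, table = tab) else k)
  }
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    labs <- cutree(hc, k = k)
    if (length(unique(labs)) < 2) return(NA_real_)
    mean(cluster::silhouette(labs, d)[, 3])
  }, numeric(1))
  tab <- tibble::tibble(k = k_range, silhouette = sil)
  if (all(is.na(sil))) {
    warn("silhouette undefined for all k; falling back to the smallest k.")
    k <- min(k_range)
  } else {
    best <- max(sil, na.rm = TRUE)
    k <- min(k_range[!is.na(sil) & sil >= best - 1e-12])
  }
  if (details) list(k = as.integer(k), table = tab) else as.integer(k)
}

welch_t <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if ((!is.finite(vx) || vx == 0) && (!is.finite(vy) || vy == 0)) {
    # both sides constant: no evidence either way unless the means differ
    return(list(p = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0,
                t = NA_real_, flag = "zero_variance"))
  }
  tt <- tryCatch(t.test(x, y), error = function(e) NULL)
  if (is.null(tt)) return(list(p = 1, t = NA_real_, flag = "degenerate"))
  list(p = tt$p.value, t = unname(tt$statistic), flag = NA_character_)
}

#' Context features associated with network subtypes
#'
#' For every feature and every subtype, a two-sided Welch t-test compares
#' the feature in that subtype against all remaining samples; each
#' feature's p-value is the minimum over subtypes, and features are ranked
#' ascending. Features that are constant everywhere get p = 1 with a flag.
#' No multiple-testing correction is applied by default (set
#' `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param context Data frame of context features; categorical columns are
#'   one-hot expanded before testing.
#' @param labels Subtype label per sample.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble: `feature`, `subtype` (argmin subtype), `t`, `p_value`,
#'   `flag`, sorted by `p_value`.
#' @export
feature_association <- function(context, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  labels <- as.character(labels)
  Cenc <- encode_context(context_schema(context), context)
  subtypes <- unique(labels)
  rows <- lapply(colnames(Cenc), function(feat) {
    x <- Cenc[, feat]
    res <- lapply(subtypes, function(s) {
      inside <- x[labels == s]; outside <- x[labels != s]
      if (length(inside) < 2 || length(outside) < 2) {
        return(list(p = NA_real_, t = NA_real_, flag = "too_few_samples"))
      }
      welch_t(inside, outside)
    })
    ps <- vapply(res, `[[`, numeric(1), "p")
    if (all(is.na(ps))) {
      return(tibble::tibble(feature = feat, subtype = NA_character_,
                            t = NA_real_, p_value = NA_real_, flag = "too_few_samples"))
    }
    best <- which.min(ps)
    tibble::tibble(feature = feat, subtype = subtypes[best],
                   t = res[[best]]$t, p_value = ps[best],
                   flag = res[[best]]$flag)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Log-rank survival stratification tests
#'
#' The k-group log-rank test (chi-squared with k-1 degrees of freedom)
#' quantifies overall stratification of survival across subtypes; all
#' pairwise two-group tests are also run, and the minimum pairwise p-value
#' reports the strongest separation between any two subtypes. Minus-log10
#' transforms are included for reporting.
#'
#' @param labels Subtype label per sample.
#' @param survival A data frame with columns `time` (nonnegative) and
#'   `event` (0 = censored, 1 = event), row-aligned with `labels`.
#' @return A list of class `logrank_result`: `chisq`, `df`,
#'   `multivariate_p`, `pairwise` (tibble), `pairwise_p` (matrix),
#'   `min_pairwise_p`, `neg_log10_multivariate`, `neg_log10_min_pairwise`,
#'   `group_counts`.
#' @export
logrank_tests <- function(labels, survival) {
  labels <- as.character(labels)
  survival <- as.data.frame(survival)
  if (!all(c("time", "event") %in% names(survival))) {
    abort("`survival` needs columns `time` and `event`.")
  }
  if (nrow(survival) != length(labels)) abort("`labels` and `survival` are misaligned.")
  keep <- is.finite(survival$time) & !is.na(labels)
  if (!all(keep)) {
    warn(sprintf("%d sample(s) with missing survival or label excluded.", sum(!keep)))
    survival <- survival[keep, , drop = FALSE]; labels <- labels[keep]
  }
  if (sum(survival$event) < 1) abort("need at least one event for a log-rank test.")
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("need at least 2 groups.")
  surv <- survival::Surv(survival$time, survival$event)
  sd_all <- survival::survdiff(surv ~ labels)
  df <- length(groups) - 1L
  p_all <- pchisq(sd_all$chisq, df = df, lower.tail = FALSE)
  pairs <- utils::combn(groups, 2)
  pmat <- matrix(NA_real_, length(groups), length(groups),
                 dimnames = list(groups, groups))
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- labels %in% c(a, b)
    p <- if (sum(survival$event[sel]) == 0) 1 else {
      sd2 <- survival::survdiff(survival::Surv(survival$time[sel], survival$event[sel]) ~ labels[sel])
      pchisq(sd2$chisq, df = 1, lower.tail = FALSE)
    }
    pmat[a, b] <<- p; pmat[b, a] <<- p
    tibble::tibble(group_a = a, group_b = b, p_value = p)
  })
  pw <- dplyr::bind_rows(pw)
  structure(list(
    chisq = unname(sd_all$chisq), df = df, multivariate_p = p_all,
    pairwise = pw, pairwise_p = pmat,
    min_pairwise_p = min(pw$p_value),
    neg_log10_multivariate = -log10(p_all),
    neg_log10_min_pairwise = -log10(min(pw$p_value)),
    group_counts = table(labels)
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> %d groups: chisq = %.3f (df %d), p = %.3g; min pairwise p = %.3g\n",
              x$df + 1L, x$chisq, x$df, x$multivariate_p, x$min_pairwise_p))
  invisible(x)
}

#' Full network-subtype discovery report
#'
#' Clusters samples on their network parameters, optionally tests which
#' context features discriminate each subtype from the rest, and optionally
#' tests survival stratification across subtypes — the complete
#' subtype-discovery pipeline on any set of per-sample networks.
#'
#' @param networks A `sample_networks` object.
#' @param context Optional context data frame for feature association.
#' @param survival Optional survival table (`time`, `event`).
#' @param k Cluster count, `"auto"` for silhouette selection, or leave as
#'   `"auto"` and supply `reference_labels` to match an existing scheme's
#'   cluster count.
#' @param reference_labels Optional reference subtype labels; when given,
#'   `k` is forced to the number of distinct reference labels.
#' @param k_range Candidate k for silhouette selection.
#' @return A list of class `subtype_report`: `clustering`,
#'   `feature_pvalues`, `logrank`, `labels`, `k`.
#' @export
subtype_report <- function(networks, context = NULL, survival = NULL,
                           k = "auto", reference_labels = NULL, k_range = 2:10) {
  if (!is.null(reference_labels)) k <- length(unique(reference_labels))
  cl <- cluster_networks(networks, k = k, k_range = k_range)
  fa <- if (!is.null(context)) feature_association(context, cl$labels) else NULL
  lr <- if (!is.null(survival)) logrank_tests(cl$labels, survival) else NULL
  structure(list(clustering = cl, feature_pvalues = fa, logrank = lr,
                 labels = cl$labels, k = cl$k),
            class = "subtype_report")
}

#' @export
print.subtype_report <- function(x, ...) {
  cat(sprintf("<subtype_report> k = %d subtypes (mean silhouette %.3f)\n",
              x$k, x$clustering$silhouette))
  if (!is.null(x$logrank)) {
    cat(sprintf("  multivariate log-rank p = %.3g; min pairwise p = %.3g\n",
                x$logrank$multivariate_p, x$logrank$min_pairwise_p))
  }
  if (!is.null(x$feature_pvalues)) {
    cat("  top features:\n")
    print(utils::head(x$feature_pvalues, 3))
  }
  invisible(x)
}
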