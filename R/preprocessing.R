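# Expression preprocessing (log transform, PCA metagenes) and plain-text
# readers/writers for matrices, networks and model bundles.

#' Log-transform nonnegative expression values
#'
#' Natural log of `x + offset` with a small offset (default 1e-3) so zeros
#' stay finite. Monotone, elementwise.
#'
#' @param X Nonnegative numeric matrix.
#' @param offset Pseudocount added before the log.
#' @param base Logarithm base (natural log by default).
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(X, offset = 1e-3, base = exp(1)) {
  X <- as.matrix(X)
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("negative expression at row %d, column %d (value %g).",
                  neg[1, 1], neg[1, 2], X[neg[1, 1], neg[1, 2]]))
  }
  log(X + offset, base = base)
}

#' Fit a metagene PCA compression on training samples
#'
#' Principal components are learned on the training split only and then
#' applied identically to any split, compressing the gene panel into `m`
#' orthonormal metagenes that become the network's node variables.
#'
#' @param X_train Training expression matrix (typically log-transformed),
#'   samples by genes.
#' @param m Number of metagenes (`m <= min(n_train, p)`).
#' @return An object of class `metagene_pca`: loadings (`rotation`),
#'   per-gene centering, `m`, and `variance_captured`.
#' @export
fit_metagenes <- function(X_train, m) {
  X_train <- as.matrix(X_train)
  if (m > min(nrow(X_train), ncol(X_train))) {
    abort(sprintf("m = %d exceeds min(n_train, p) = %d.",
                  m, min(nrow(X_train), ncol(X_train))))
  }
  pc <- prcomp(X_train, center = TRUE, scale. = FALSE)
  totvar <- sum(pc$sdev^2)
  vc <- if (totvar > 0) sum(pc$sdev[seq_len(m)]^2) / totvar else 1
  structure(list(rotation = pc$rotation[, seq_len(m), drop = FALSE],
                 center = pc$center, m = m,
                 variance_captured = vc),
            class = "metagene_pca")
}

#' @describeIn fit_metagenes Project expression onto the fitted metagenes.
#' @param state A `metagene_pca`.
#' @param X Expression matrix with the original gene panel.
#' @export
apply_metagenes <- function(state, X) {
  stopifnot(inherits(state, "metagene_pca"))
  X <- as.matrix(X)
  if (ncol(X) != length(state$center)) {
    abort(sprintf("X has %d genes but the PCA was fitted on %d.",
                  ncol(X), length(state$center)))
  }
  sweep(X, 2, state$center) %*% state$rotation
}

#' @describeIn fit_metagenes Back-project metagene scores to the gene panel.
#' @param scores An `n x m` metagene score matrix.
#' @export
invert_metagenes <- function(state, scores) {
  stopifnot(inherits(state, "metagene_pca"))
  sweep(scores %*% t(state$rotation), 2, state$center, "+")
}

#' Read / write a samples-by-features matrix as delimited text
#'
#' Tab-delimited with a header row of feature ids and the first column
#' holding sample ids; `read_matrix(write_matrix(x))` round-trips exactly.
#'
#' @param path File path.
#' @return For `read_matrix()`, a numeric matrix with sample ids as row
#'   names.
#' @export
read_matrix <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("ragged row in '%s' at line %d (%d fields, expected %d).",
                  path, bad, nf[bad], nf[1]))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("duplicate sample id(s) in '%s': %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) abort(sprintf("missing values in '%s'; supply complete data.", path))
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param x Numeric matrix with row names as sample ids (or they are
#'   generated).
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  df <- data.frame(sample_id = ids, x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read per-sample networks as long-format text
#'
#' One row per (sample, gene pair): `sample_id`, `gene_i`, `gene_j`,
#' `value`, `network_class`. Diagonal entries are omitted for the
#' diagonal-masked classes (neighborhood, markov) where they are zero by
#' construction.
#'
#' @param networks A `sample_networks` object.
#' @param path File path.
#' @export
write_networks <- function(networks, path) {
  stopifnot(inherits(networks, "sample_networks"))
  df <- tidy(networks)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_networks
#' @export
read_networks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  cls <- unique(df$network_class)
  if (length(cls) != 1) abort("network file mixes network classes.")
  genes <- sort(unique(c(df$gene_i, df$gene_j)))
  samples <- unique(df$sample_id)
  p <- length(genes)
  arr <- array(0, dim = c(length(samples), p, p),
               dimnames = list(samples, genes, genes))
  arr[cbind(match(df$sample_id, samples),
            match(df$gene_i, genes),
            match(df$gene_j, genes))] <- df$value
  sample_networks(arr, cls, gene_ids = genes, sample_ids = samples)
}

#' Save / load a fitted model bundle
#'
#' Serializes the full model state (encoder weights, archetypes, context
#' schema, gene ordering, standardization statistics, configuration and
#' seed) with a format version tag. Bundles contain no timestamps, so the
#' same fit always writes byte-identical files.
#'
#' @param fit A `ctxnet_fit`, `ctxnet_ensemble` or `grouped_fit`.
#' @param path File path for the bundle.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, c("ctxnet_fit", "ctxnet_ensemble", "grouped_fit")))
  saveRDS(list(format = "ctxnet_bundle", version = 1L, model = fit),
          path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("'%s' is not a ctxnet model bundle (%s).", path,
                  conditionMessage(e)))
  })
  if (!identical(bundle$format, "ctxnet_bundle")) {
    abort(sprintf("'%s' is not a ctxnet model bundle.", path))
  }
  bundle$model
}
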