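#' Fit a context-encoding schema on training samples
#'
#' Converts a data frame of mixed sample metadata into the numeric design
#' matrix consumed by the context encoder. Continuous columns are z-scored
#' with training-split statistics; missing continuous values are
#' mean-imputed and flagged with a companion missingness-indicator column;
#' categorical columns (factor/character/logical) are one-hot encoded with
#' an explicit `NA` level. The schema is frozen at fit time and reapplied
#' verbatim at prediction time, so train/test transforms are identical.
#'
#' @param context A data frame (or matrix) of per-sample context features.
#' @return An object of class `context_schema`.
#' @seealso [encode_context()]
#' @export
context_schema <- function(context) {
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  if (ncol(context) == 0) abort("`context` has no columns.")
  cols <- lapply(names(context), function(nm) {
    x <- context[[nm]]
    if (is.numeric(x)) {
      if (any(is.infinite(x))) abort(sprintf("context feature '%s' has non-finite values.", nm))
      mu <- mean(x, na.rm = TRUE)
      if (!is.finite(mu)) mu <- 0
      sdev <- sd(x, na.rm = TRUE)
      if (!is.finite(sdev) || sdev == 0) sdev <- 1
      list(name = nm, kind = "numeric", mean = mu, sd = sdev,
           has_na = anyNA(x))
    } else {
      levs <- sort(unique(as.character(x)))
      levs <- levs[!is.na(levs)]
      if (anyNA(x)) levs <- c(levs, NA_character_)
      list(name = nm, kind = "categorical", levels = levs)
    }
  })
  structure(list(columns = cols, names = names(context)), class = "context_schema")
}

#' Encode context features with a fitted schema
#'
#' @param schema A [context_schema()].
#' @param context A data frame with the same columns as at fit time.
#' @return A numeric matrix, one row per sample.
#' @export
encode_context <- function(schema, context) {
  stopifnot(inherits(schema, "context_schema"))
  context <- as.data.frame(context, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema$names, names(context))
  if (length(missing_cols)) {
    abort(paste0("context is missing feature(s): ", paste(missing_cols, collapse = ", ")))
  }
  blocks <- lapply(schema$columns, function(col) {
    x <- context[[col$name]]
    if (col$kind == "numeric") {
      if (!is.numeric(x)) abort(sprintf("context feature '%s' must be numeric.", col$name))
      if (any(is.infinite(x))) abort(sprintf("context feature '%s' has non-finite values.", col$name))
      miss <- is.na(x)
      x[miss] <- col$mean
      z <- (x - col$mean) / col$sd
      if (col$has_na) {
        out <- cbind(z, as.numeric(miss))
        colnames(out) <- c(col$name, paste0(col$name, "__missing"))
      } else {
        if (any(miss)) abort(sprintf("context feature '%s' has unexpected missing values.", col$name))
        out <- matrix(z, ncol = 1, dimnames = list(NULL, col$name))
      }
      out
    } else {
      xc <- as.character(x)
      known <- xc %in% col$levels[!is.na(col$levels)]
      bad <- !known & !is.na(xc)
      if (any(bad) || (anyNA(xc) && !anyNA(col$levels))) {
        abort(sprintf("context feature '%s' has level(s) unseen at fit time: %s",
                      col$name,
                      paste(unique(c(xc[bad], if (anyNA(xc) && !anyNA(col$levels)) "NA")),
                            collapse = ", ")))
      }
      out <- vapply(col$levels, function(lv) {
        if (is.na(lv)) as.numeric(is.na(xc)) else as.numeric(!is.na(xc) & xc == lv)
      }, numeric(length(xc)))
      out <- matrix(out, nrow = length(xc))
      colnames(out) <- paste0(col$name, "=", ifelse(is.na(col$levels), "NA", col$levels))
      out
    }
  })
  mat <- do.call(cbind, blocks)
  rownames(mat) <- rownames(context)
  mat
}
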