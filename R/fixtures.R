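# Planted-subtype synthetic cohorts: context-predictable network variation
# plus survival-stratified subtypes, mirroring the statistical structure of
# a heterogeneous tumor cohort without requiring any external data.

#' Specify a planted-subtype cohort
#'
#' Each subtype has its own precision matrix (a random sparse symmetric
#' matrix, diagonally loaded to be safely positive definite); expression is
#' drawn from the corresponding Gaussian; context features carry the
#' subtype signal with configurable informativeness plus pure-noise
#' features; survival times are exponential with subtype-specific hazard
#' rates under independent exponential censoring.
#'
#' @param n_subtypes Number of planted subtypes.
#' @param p Number of genes.
#' @param n_per_subtype Samples per subtype (recycled; a 0 omits a subtype
#'   with a warning).
#' @param informativeness In `[0, 1]`: fraction of the subtype signal
#'   carried by the informative context features (0 = context carries no
#'   subtype information).
#' @param n_noise_features Count of uninformative standard-normal context
#'   features.
#' @param noise_sd Noise added to the informative context features.
#' @param hazard_rates Per-subtype exponential hazard rates (events per
#'   unit time).
#' @param censor_rate Rate of the independent exponential censoring time
#'   (default gives roughly 20% censoring for unit hazards).
#' @param edge_strength Magnitude of planted off-diagonal partial
#'   correlations.
#' @param seed RNG seed.
#' @return A `planted_cohort_spec` list.
#' @export
planted_cohort_spec <- function(n_subtypes = 3, p = 8, n_per_subtype = 100,
                                informativeness = 1, n_noise_features = 3,
                                noise_sd = 0.1,
                                hazard_rates = 2^(seq_len(n_subtypes) - 1),
                                censor_rate = 0.25 * mean(hazard_rates),
                                edge_strength = 0.4, seed = 1) {
  stopifnot(n_subtypes >= 1, p >= 2, all(hazard_rates > 0),
            informativeness >= 0, informativeness <= 1)
  structure(list(n_subtypes = n_subtypes, p = p,
                 n_per_subtype = rep(n_per_subtype, length.out = n_subtypes),
                 informativeness = informativeness,
                 n_noise_features = n_noise_features, noise_sd = noise_sd,
                 hazard_rates = hazard_rates, censor_rate = censor_rate,
                 edge_strength = edge_strength, seed = seed),
            class = "planted_cohort_spec")
}

# Random sparse symmetric precision with unit diagonal after rescaling;
# diagonal loading keeps the condition number bounded.
random_precision <- function(p, edge_strength, max_condition = 100) {
  mask <- upper.tri(diag(p)) & matrix(runif(p * p) < 0.4, p, p)
  B <- matrix(0, p, p)
  B[mask] <- sample(c(-1, 1), sum(mask), replace = TRUE) * edge_strength
  B <- B + t(B)
  omega <- B
  diag(omega) <- 1
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev); hi <- max(ev)
  if (lo <= hi / max_condition) {
    load <- (hi - max_condition * lo) / (max_condition - 1)
    omega <- omega + diag(load, p)
  }
  unit_diag_scale(omega)
}

#' Generate a planted-subtype cohort
#'
#' @param spec A [planted_cohort_spec()].
#' @return A list: `context` (tibble with informative `subtype_signal_*`
#'   and `noise_*` columns), `expression` (`n x p` matrix), `labels`
#'   (planted subtype per sample), `survival` (tibble: `sample_id`, `time`,
#'   `event`), `true_precision` (`n x p x p` array) and
#'   `archetype_precisions` (per-subtype list).
#' @export
generate_planted_cohort <- function(spec) {
  stopifnot(inherits(spec, "planted_cohort_spec"))
  set.seed(spec$seed)
  keep <- spec$n_per_subtype > 0
  if (any(!keep)) {
    warn(sprintf("subtype(s) %s omitted (0 samples requested).",
                 paste(which(!keep), collapse = ", ")))
  }
  subtypes <- which(keep)
  p <- spec$p
  omegas <- lapply(seq_len(spec$n_subtypes), function(s) {
    random_precision(p, spec$edge_strength)
  })
  labels <- rep(subtypes, times = spec$n_per_subtype[keep])
  n <- length(labels)
  ord <- sample.int(n)  # interleave subtypes so sample order carries no signal
  labels <- labels[ord]
  X <- matrix(0, n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  truth <- array(0, dim = c(n, p, p))
  for (s in subtypes) {
    rows <- which(labels == s)
    sigma <- solve(omegas[[s]])
    L <- chol(sigma)
    X[rows, ] <- matrix(rnorm(length(rows) * p), length(rows), p) %*% L
    for (i in rows) truth[i, , ] <- omegas[[s]]
  }
  # informative context: scaled subtype one-hot plus noise, then pure noise
  onehot <- vapply(subtypes, function(s) as.numeric(labels == s), numeric(n))
  info <- spec$informativeness * onehot +
    matrix(rnorm(n * length(subtypes), sd = spec$noise_sd), n)
  noise <- matrix(rnorm(n * spec$n_noise_features), n)
  context <- tibble::as_tibble(
    setNames(as.data.frame(cbind(info, noise)),
             c(paste0("subtype_signal_", subtypes),
               paste0("noise_", seq_len(spec$n_noise_features)))))
  t_event <- rexp(n, rate = spec$hazard_rates[labels])
  t_cens <- rexp(n, rate = spec$censor_rate)
  survival <- tibble::tibble(sample_id = as.character(seq_len(n)),
                             time = pmin(t_event, t_cens),
                             event = as.integer(t_event <= t_cens))
  list(context = context,
       expression = X,
       labels = labels,
       survival = survival,
       true_precision = sample_networks(truth, "precision",
                                        gene_ids = colnames(X)),
       archetype_precisions = omegas)
}
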