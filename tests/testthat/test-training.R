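test_that("homogeneous-limit training converges to the OLS solution", {
  set.seed(8)
  p <- 4; n <- 400
  Sig <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.5
  X <- matrix(rnorm(n * p), n) %*% chol(Sig)
  ctx <- data.frame(const = rep(1, n))
  fit <- contextualized_fit(X, ctx, network_class = "neighborhood", K = 1,
                            lambda = 0, hidden_widths = integer(0),
                            learning_rate = 1e-2, max_epochs = 2500,
                            patience = 2500, restore_best = FALSE, seed = 7)
  # oracle: closed-form OLS on the same standardized training split
  Xs <- standardize_like(fit, X)
  set.seed(ctxnet:::derive_seed(7, 1))
  val <- sort(sample.int(n, floor(0.2 * n)))
  th_ols <- mask_diagonal(ols_neighborhood(Xs[-val, , drop = FALSE]))
  ols_val <- mean((Xs[val, ] - Xs[val, ] %*% th_ols)^2)
  ols_train <- mean((Xs[-val, ] - Xs[-val, ] %*% th_ols)^2)
  expect_lt(abs(fit$val_loss - ols_val), 1e-3)
  # at convergence the training loss attains the closed-form optimum
  expect_lt(abs(fit$final_train_loss - ols_train), 1e-6)
})

test_that("the fitted 2-gene Markov edge tracks the true context", {
  dat <- sample_cvg(cvg_spec(n_contexts = 800, samples_per_context = 1, seed = 31))
  fit <- contextualized_fit(dat$expression, dat$context, network_class = "markov",
                            K = 4, lambda = 0, hidden_widths = c(16, 16),
                            learning_rate = 5e-3, max_epochs = 300,
                            patience = 25, seed = 3)
  hold <- sample_cvg(cvg_spec(n_contexts = 300, samples_per_context = 1, seed = 99))
  nets <- predict(fit, hold$context)
  edge <- nets[, 1, 2] + nets[, 2, 1]  # symmetrized regression coefficient
  expect_gt(cor(edge, hold$context$context), 0.95)
})

test_that("prediction is deterministic, cached at fit time, and schema-checked", {
  set.seed(5)
  X <- matrix(rnorm(120), 60, 2)
  ctx <- data.frame(c1 = rnorm(60))
  fit <- contextualized_fit(X, ctx, network_class = "neighborhood", K = 2,
                            hidden_widths = c(8), max_epochs = 30,
                            patience = 30, seed = 1)
  # training-context predictions equal the cached networks
  expect_equal(unclass(predict(fit, ctx)), unclass(fit$training_networks),
               ignore_attr = TRUE)
  # duplicated context rows give duplicated networks
  two <- predict(fit, data.frame(c1 = c(0.4, 0.4)))
  expect_identical(two[1, , ], two[2, , ])
  # schema mismatch names the offending feature
  expect_error(predict(fit, data.frame(wrong = 1)), "c1")
})

test_that("training is reproducible and aborts cleanly on divergence", {
  set.seed(9)
  X <- matrix(rnorm(100), 50, 2)
  ctx <- data.frame(c1 = rnorm(50))
  f1 <- contextualized_fit(X, ctx, K = 2, hidden_widths = c(8),
                           max_epochs = 25, patience = 25, seed = 11)
  f2 <- contextualized_fit(X, ctx, K = 2, hidden_widths = c(8),
                           max_epochs = 25, patience = 25, seed = 11)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$archetypes, f2$archetypes)
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(contextualized_fit(Xbad, ctx, K = 2, seed = 1),
               "non-finite")
  expect_error(
    contextualized_fit(X, ctx, K = 2, hidden_widths = c(8),
                       learning_rate = 1e200, max_epochs = 5,
                       standardize = FALSE, seed = 1),
    "non-finite loss")
})

test_that("training loss is non-increasing up to optimizer tolerance", {
  set.seed(13)
  dat <- sample_cvg(cvg_spec(n_contexts = 200, samples_per_context = 1, seed = 5))
  fit <- contextualized_fit(dat$expression, dat$context, network_class = "neighborhood",
                            K = 2, lambda = 0, hidden_widths = c(8),
                            learning_rate = 2e-3, max_epochs = 120,
                            patience = 120, seed = 2)
  tr <- fit$trace$train_loss
  increases <- diff(tr)[diff(tr) > 0]
  expect_lt(sum(increases), 0.02 * tr[1])  # tiny Adam oscillations only
})

test_that("a richer archetype family fits heterogeneous data no worse", {
  dat <- sample_cvg(cvg_spec(n_contexts = 500, samples_per_context = 1, seed = 17))
  args <- list(expression = dat$expression, context = dat$context,
               network_class = "markov", lambda = 0, hidden_widths = c(16),
               learning_rate = 5e-3, max_epochs = 200, patience = 200)
  f1 <- do.call(contextualized_fit, c(args, list(K = 1, seed = 4)))
  f16 <- do.call(contextualized_fit, c(args, list(K = 16, seed = 4)))
  expect_lte(f16$val_loss, f1$val_loss + 1e-3)
})

test_that("bootstrap ensembles aggregate member networks", {
  set.seed(19)
  X <- matrix(rnorm(160), 80, 2)
  ctx <- data.frame(c1 = rnorm(80))
  args <- list(network_class = "neighborhood", K = 2, hidden_widths = c(8),
               max_epochs = 25, patience = 25)
  # B = 1: no resampling, ensemble == the single fit with the same seed
  ens1 <- do.call(bootstrap_fit, c(list(X, ctx, B = 1, seed = 3), args))
  single <- do.call(contextualized_fit, c(list(X, ctx, seed = 3), args))
  expect_equal(unclass(predict(ens1, ctx)), unclass(predict(single, ctx)),
               ignore_attr = TRUE)
  expect_equal(max(abs(attr(predict(ens1, ctx), "sd"))), 0)

  ens3 <- do.call(bootstrap_fit, c(list(X, ctx, B = 3, seed = 3), args))
  pr <- predict(ens3, ctx)
  manual <- Reduce(`+`, lapply(ens3$members, function(m) unclass(predict(m, ctx)))) / 3
  expect_equal(unclass(pr), manual, ignore_attr = TRUE)
  expect_true(all(attr(pr, "sd") >= 0))
})

test_that("bootstrap averaging does not inflate parameter error", {
  # variance-reduction property: the ensemble's parameter MSE is at most
  # about the median member's, across replicate simulated experiments
  wins <- 0
  for (rep in 1:5) {
    dat <- sample_cvg(cvg_spec(n_contexts = 150, samples_per_context = 1,
                               seed = 40 + rep))
    ens <- bootstrap_fit(dat$expression, dat$context, B = 3,
                         network_class = "markov", K = 2,
                         hidden_widths = c(8), learning_rate = 5e-3,
                         max_epochs = 120, patience = 120, seed = rep)
    ens_mse <- parameter_mse(network_precision(predict(ens, dat$context)),
                             dat$true_precision)
    member_mse <- vapply(ens$members, function(m) {
      parameter_mse(network_precision(predict(m, dat$context)), dat$true_precision)
    }, numeric(1))
    if (ens_mse <= median(member_mse) + 1e-6) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
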