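make_two_blob_networks <- function(n_per = 20, sep = 10, seed = 1) {
  set.seed(seed)
  flat <- rbind(
    matrix(rnorm(n_per * 4, mean = 0, sd = 0.1), n_per, 4),
    matrix(rnorm(n_per * 4, mean = sep, sd = 0.1), n_per, 4))
  arr <- array(0, c(2 * n_per, 3, 3))
  idx <- which(upper.tri(diag(3)) | lower.tri(diag(3)))[1:4]
  for (i in seq_len(2 * n_per)) {
    m <- matrix(0, 3, 3); m[idx] <- flat[i, ]; arr[i, , ] <- m
  }
  sample_networks(arr, "neighborhood")
}

test_that("Ward clustering recovers planted network groups exactly", {
  nets <- make_two_blob_networks()
  truth <- rep(1:2, each = 20)
  cl <- cluster_networks(nets, k = 2)
  expect_equal(adjusted_rand(cl$labels, truth), 1.0)
  # label assignment is invariant to sample order up to renaming
  perm <- sample(40)
  cl_perm <- cluster_networks(sample_networks(unclass(nets)[perm, , ],
                                              "neighborhood"), k = 2)
  expect_equal(adjusted_rand(cl_perm$labels, truth[perm]), 1.0)
})

test_that("identical networks give a degenerate flagged split", {
  arr <- array(1, c(10, 2, 2))
  nets <- sample_networks(arr, "correlation")
  expect_warning(cl <- cluster_networks(nets, k = 2), "silhouette|degenerate")
  expect_equal(cl$k, 2L)
})

test_that("silhouette selection finds the planted number of clusters", {
  # 1-D values {0, 0.1, 10, 10.1}: k = 2 splits the two pairs with
  # silhouette ~0.99 (direct formula oracle), higher k fragments pairs
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  sel <- select_k_silhouette(x, k_range = 2:3, details = TRUE)
  expect_equal(sel$k, 2L)
  sil2 <- sel$table$silhouette[sel$table$k == 2]
  # direct silhouette oracle: s_i = (b_i - a_i) / max(a_i, b_i) with
  # a_i = 0.1 and b_i the mean distance to the opposite pair
  expect_equal(sil2, mean(1 - 0.1 / c(10.05, 9.95, 9.95, 10.05)),
               tolerance = 1e-10)
  expect_gt(sil2, 0.98)

  # three tight equidistant blobs select k = 3
  set.seed(2)
  blobs <- rbind(matrix(rnorm(40, 0, .05), 20), matrix(rnorm(40, 5, .05), 20),
                 matrix(rnorm(40, 10, .05), 20))
  expect_equal(select_k_silhouette(blobs, 2:6), 3L)

  # identical points: undefined silhouette falls back to smallest k
  expect_warning(k0 <- select_k_silhouette(matrix(1, 8, 2), 2:4), "identical")
  expect_equal(k0, 2L)
  expect_error(select_k_silhouette(matrix(1, 2, 2)), "more than 2")
})

test_that("feature association reproduces the textbook t-test", {
  labels <- rep(c("s1", "rest"), each = 3)
  ctx <- data.frame(f = c(5, 6, 7, 0, 1, 2))
  out <- feature_association(ctx, labels)
  # equal sizes and variances: Welch equals the pooled t = 6.124, df = 4
  expect_equal(abs(out$t[1]), 6.124, tolerance = 1e-3)
  t_oracle <- pooled_t(c(5, 6, 7), c(0, 1, 2))
  expect_equal(abs(t_oracle), 6.123724, tolerance = 1e-6)
  # with equal sizes and variances Welch reduces to the pooled test, df = 4
  expect_equal(out$p_value[1], 2 * pt(-abs(t_oracle), df = 4), tolerance = 1e-6)

  # constant feature: p = 1 with flag
  ctx2 <- data.frame(f = c(5, 6, 7, 0, 1, 2), const = rep(3, 6))
  out2 <- feature_association(ctx2, labels)
  row_const <- out2[out2$feature == "const", ]
  expect_equal(row_const$p_value, 1)
  expect_equal(row_const$flag, "zero_variance")
})

test_that("feature p-values are uniform under label permutation", {
  set.seed(9)
  x <- data.frame(f = rnorm(40))
  ps <- vapply(1:200, function(i) {
    labs <- sample(rep(c("a", "b"), 20))
    feature_association(x, labs)$p_value[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("log-rank tests match a brute-force observed-vs-expected oracle", {
  # identical survival in both groups: statistic 0, p = 1
  surv_same <- data.frame(time = rep(c(1, 2, 3), 2), event = 1)
  labs <- rep(c("a", "b"), each = 3)
  res <- logrank_tests(labs, surv_same)
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$multivariate_p, 1, tolerance = 1e-8)

  # separated event times: compare against hand enumeration
  surv <- data.frame(time = c(1, 2, 3, 10, 20, 30), event = 1)
  res2 <- logrank_tests(labs, surv)
  chisq_oracle <- logrank_chisq_brute(surv$time, surv$event, labs)
  expect_equal(res2$chisq, chisq_oracle, tolerance = 1e-6)
  expect_equal(res2$multivariate_p, pchisq(chisq_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res2$min_pairwise_p, res2$multivariate_p, tolerance = 1e-10)
  expect_equal(res2$neg_log10_multivariate, -log10(res2$multivariate_p))

  # three groups, two identical: the distinct pair attains the minimum
  surv3 <- data.frame(time = c(1, 2, 3, 1, 2, 3, 30, 40, 50), event = 1)
  labs3 <- rep(c("a", "b", "c"), each = 3)
  res3 <- logrank_tests(labs3, surv3)
  pw <- res3$pairwise
  pmin_pair <- pw[which.min(pw$p_value), ]
  expect_true("c" %in% c(pmin_pair$group_a, pmin_pair$group_b))
  expect_equal(res3$pairwise_p["a", "b"], 1, tolerance = 1e-6)
})

test_that("log-rank type-I error is calibrated under label shuffles", {
  set.seed(21)
  n <- 60
  surv <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8))
  hits <- 0
  for (i in 1:400) {
    labs <- sample(rep(c("a", "b"), n / 2))
    p <- logrank_tests(labs, surv)$multivariate_p
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 400, 0.07)
})

test_that("the full subtype report combines clustering, features and survival", {
  nets <- make_two_blob_networks(n_per = 15, seed = 3)
  truth <- rep(1:2, each = 15)
  set.seed(4)
  ctx <- data.frame(signal = truth + rnorm(30, sd = 0.2), junk = rnorm(30))
  surv <- data.frame(time = rexp(30, rate = c(4, 0.5)[truth]),
                     event = 1)
  rep_ <- subtype_report(nets, context = ctx, survival = surv, k = "auto",
                         k_range = 2:5)
  expect_equal(rep_$k, 2L)
  expect_equal(adjusted_rand(rep_$labels, truth), 1.0)
  expect_equal(rep_$feature_pvalues$feature[1], "signal")
  expect_lt(rep_$logrank$multivariate_p, 0.01)
  g <- glance(rep_)
  expect_equal(g$k, 2L)
  expect_equal(g$top_feature, "signal")
  # forcing k from reference labels
  rep3 <- subtype_report(nets, reference_labels = rep(1:3, 10))
  expect_equal(rep3$k, 3L)
})
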