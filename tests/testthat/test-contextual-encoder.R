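make_linear_fit <- function(W, b = NULL, A, mode = "linear", gene_ids = NULL) {
  # assemble a minimal fitted state by hand: identity schema over numeric
  # context columns, a zero-hidden-layer encoder, fixed archetypes
  K <- nrow(A); p <- as.integer(sqrt(ncol(A)))
  d <- nrow(W)
  ctx <- as.data.frame(matrix(rnorm(5 * d), 5))
  schema <- context_schema(ctx)
  for (i in seq_along(schema$columns)) {
    schema$columns[[i]]$mean <- 0
    schema$columns[[i]]$sd <- 1
  }
  structure(list(
    network_class = "neighborhood", K = K, p = p, d = d,
    gene_ids = gene_ids %||% paste0("g", seq_len(p)),
    mode = mode, hidden_widths = integer(0),
    encoder = list(W = list(W), b = list(b %||% rep(0, K)),
                   hidden = integer(0), K = K),
    archetypes = A, schema = schema,
    center = rep(0, p), scale = rep(1, p), standardize = FALSE,
    lambda = 0, seed = 1
  ), class = "ctxnet_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("context schema one-hot encodes categoricals and freezes statistics", {
  df <- data.frame(age = c(1, 2, 3, NA), tissue = c("a", "b", "a", NA),
                   stringsAsFactors = FALSE)
  sc <- context_schema(df)
  M <- encode_context(sc, df)
  expect_true(all(is.finite(M)))
  expect_true("age__missing" %in% colnames(M))
  expect_setequal(grep("tissue", colnames(M), value = TRUE),
                  c("tissue=a", "tissue=b", "tissue=NA"))
  # one-hot rows sum to one over each categorical block
  expect_equal(unname(rowSums(M[, grep("tissue", colnames(M))])), rep(1, 4))
  # transform is frozen: encoding a subset uses fit-time statistics
  expect_equal(M[1:2, ], encode_context(sc, df[1:2, ])[, ], ignore_attr = TRUE)
  # unseen level is an explicit, named error
  expect_error(encode_context(sc, data.frame(age = 1, tissue = "z")),
               "tissue.*unseen")
  expect_error(encode_context(sc, data.frame(age = 1)), "missing feature")
})

test_that("a linear identity encoder passes context through as subtype weights", {
  K <- 3
  A <- matrix(rnorm(K * 4), K, 4)
  fit <- make_linear_fit(diag(K), A = A)
  Z <- subtype_weights(fit, data.frame(V1 = 1, V2 = 0, V3 = 0))
  expect_equal(as.vector(Z), c(1, 0, 0))
  # determinism: same context, same weights
  expect_identical(Z, subtype_weights(fit, data.frame(V1 = 1, V2 = 0, V3 = 0)))
})

test_that("simplex mode returns uniform weights for all-equal pre-activations", {
  K <- 4
  A <- matrix(0, K, 4)
  fit <- make_linear_fit(matrix(0, 2, K), A = A, mode = "simplex")
  Z <- subtype_weights(fit, data.frame(V1 = c(2, -1), V2 = c(0, 5)))
  expect_equal(unname(Z), matrix(1 / K, 2, K))
  expect_equal(unname(rowSums(Z)), c(1, 1), tolerance = 1e-12)
})

test_that("mix_archetypes is the weighted sum of archetypes and linear in Z", {
  A <- list(matrix(c(0, 1, 1, 0), 2), matrix(c(0, -1, -1, 0), 2))
  expect_equal(mix_archetypes(c(1, 0), A), A[[1]])
  expect_equal(mix_archetypes(c(0.5, 0.5), A), matrix(0, 2, 2))
  Z <- c(0.3, -0.7)
  expect_equal(mix_archetypes(2.5 * Z, A), 2.5 * mix_archetypes(Z, A))
  expect_error(mix_archetypes(c(1, 2, 3), A), "archetypes")
})

test_that("contextualization composes encode, mix and class masking", {
  K <- 2
  A <- rbind(as.vector(matrix(c(9, 1, 2, 9), 2)),
             as.vector(matrix(c(9, -1, 4, 9), 2)))
  fit <- make_linear_fit(diag(K), A = A)
  nets <- predict(fit, data.frame(V1 = c(1, 0, 1), V2 = c(0, 1, 1)))
  # one-hot contexts select single archetypes, diagonal masked to zero
  expect_equal(nets[1, , ], matrix(c(0, 1, 2, 0), 2), ignore_attr = TRUE)
  expect_equal(nets[2, , ], matrix(c(0, -1, 4, 0), 2), ignore_attr = TRUE)
  expect_equal(nets[3, , ], matrix(c(0, 0, 6, 0), 2), ignore_attr = TRUE)
  # identical contexts give identical networks
  same <- predict(fit, data.frame(V1 = c(1, 1), V2 = c(0, 0)))
  expect_identical(same[1, , ], same[2, , ])
})

test_that("emitted networks lie in the archetype span and are affine in context", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  ctx <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  fit <- contextualized_fit(X, ctx, network_class = "neighborhood", K = 3,
                            lambda = 0, hidden_widths = integer(0),
                            max_epochs = 30, patience = 30, seed = 5)
  nets <- predict(fit, ctx)
  A <- fit$archetypes
  for (i in c(1, 17, 42)) {
    v <- as.vector(nets[i, , ])
    v_keep <- v[-ctxnet:::diag_cols(3)]
    Am <- t(A)[-ctxnet:::diag_cols(3), , drop = FALSE]
    resid <- v_keep - Am %*% qr.coef(qr(Am), v_keep)
    expect_lt(max(abs(resid)), 1e-8)
  }
  # linear encoder => networks affine in C: finite differences are constant
  probe <- function(c1) predict(fit, data.frame(c1 = c1, c2 = 0.3))[1, 1, 2]
  d1 <- probe(0.1) - probe(0.0)
  d2 <- probe(0.6) - probe(0.5)
  d3 <- probe(-0.2) - probe(-0.3)
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1, d3, tolerance = 1e-9)
})

test_that("K = 1 simplex collapses to a single context-independent network", {
  set.seed(3)
  X <- matrix(rnorm(80), 40, 2)
  ctx <- data.frame(c1 = rnorm(40))
  fit <- contextualized_fit(X, ctx, network_class = "neighborhood", K = 1,
                            mode = "simplex", lambda = 0,
                            hidden_widths = c(8), max_epochs = 40,
                            patience = 40, seed = 2)
  nets <- predict(fit, data.frame(c1 = c(-5, 0, 5)))
  expect_equal(nets[1, , ], nets[2, , ])
  expect_equal(nets[2, , ], nets[3, , ])
})
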