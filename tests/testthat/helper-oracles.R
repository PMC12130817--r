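# Independent oracles used across the suite. Each reimplements the quantity
# under test by a different route (closed form, enumeration, or a reference
# library call) so that agreement is informative.

# Column-wise OLS neighborhood solution via lm() per gene.
ols_neighborhood <- function(X) {
  p <- ncol(X)
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    df <- as.data.frame(X)
    names(df) <- paste0("v", seq_len(p))
    co <- coef(lm(df[[j]] ~ . - 1, data = df[, -j, drop = FALSE]))
    theta[-j, j] <- unname(co)
  }
  theta
}

# Partial correlation of (i, j) given the rest, from the conditional
# covariance of a bivariate block: C = S_ab - S_aR S_RR^{-1} S_Rb.
partial_cor_conditional <- function(omega) {
  sigma <- solve(omega)
  p <- nrow(omega)
  out <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rest <- setdiff(seq_len(p), c(i, j))
    if (length(rest)) {
      Sab <- sigma[c(i, j), c(i, j)]
      SaR <- sigma[c(i, j), rest, drop = FALSE]
      Cc <- Sab - SaR %*% solve(sigma[rest, rest, drop = FALSE]) %*% t(SaR)
    } else {
      Cc <- sigma[c(i, j), c(i, j)]
    }
    out[i, j] <- out[j, i] <- Cc[1, 2] / sqrt(Cc[1, 1] * Cc[2, 2])
  }
  out
}

random_spd <- function(p) {
  B <- matrix(rnorm(p * p), p)
  crossprod(B) + diag(p) * 0.5
}

# Two-group log-rank test by direct enumeration of the observed-vs-expected
# table over distinct event times (no censoring adjustments beyond risk
# sets), returning the chi-squared statistic.
logrank_chisq_brute <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == groups[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Pooled two-sample t statistic (textbook form).
pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Adjusted Rand index between two labelings (standard contingency formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Deterministic 2-gene dataset with exact zero means, unit mean-square
# columns and exact empirical correlation r (population convention).
bivariate_with_cor <- function(r, reps = 1) {
  z1 <- rep(c(1, 1, -1, -1), reps)
  z2 <- rep(c(1, -1, 1, -1), reps)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}
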