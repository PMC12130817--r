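---
title: "Contextualized network inference: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualized network inference: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk transcriptomic cohorts are heterogeneous: the gene–gene dependency
structure of a tumor sample depends on tissue, copy-number state, immune
infiltration and other per-sample covariates. Classical network estimators
ignore this (one population network), or discretize it (one network per
cohort or per context cluster), which either averages away heterogeneity or
starves each group of samples. `ctxnet` instead treats the network as a
*function of context*: a learned encoder maps each sample's metadata
$C \in \mathbb{R}^d$ to the parameters of that sample's own Gaussian
graphical model, so every sample gets its own network while all samples
share statistical strength through the encoder.

## Model

All three supported network classes are expressed through one linear
parameterization, a square coefficient matrix $\theta \in \mathbb{R}^{p\times p}$
scored by regression residuals on expression $X \in \mathbb{R}^{n \times p}$:

* **Neighborhood selection**: every gene is regressed on all others,
  $\ell_{NN} = \lVert X - X\theta' \rVert^2 + \lambda \sum_i \lVert \theta'_i \rVert_1$,
  where $\theta' = (1 - I) \odot \theta$ masks the diagonal so a gene never
  predicts itself. Nonzero $\theta'_{ij}$ are directed edges.
* **Markov (precision) networks**: assuming a unit-diagonal precision
  matrix, the regression matrix is symmetric, which we encode as
  $\theta = \gamma' + \gamma'^{\top}$ with masked $\gamma'$ and loss
  $\ell_{MN} = \lVert X - X(\gamma' + \gamma'^{\top}) \rVert^2 + \lambda \sum_i \lVert \gamma'_i \rVert_1$.
  The precision estimate is $\hat\Omega = -(\gamma' + \gamma'^{\top})$ with
  unit diagonal, and partial correlations follow as
  $\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}$.
* **Correlation networks**: each ordered gene pair is a univariate
  regression, $\ell_{CN} = \lVert X - X \odot \theta \rVert_F^2$ over pairs,
  whose optimum recovers squared Pearson correlations as
  $\hat\rho^2_{ij} = \theta_{ij}\theta_{ji}$. No sparsity term is used for
  this class.

Contextualization replaces the shared $\theta$ by a per-sample
$\theta_n = \sum_{k=1}^{K} f(C_n)_k A_k$: a dictionary of $K$ learnable
archetype matrices $A_k$, mixed by subtype weights $Z = f(C)$ from a
multilayer-perceptron encoder. Everything — encoder weights and archetypes —
is trained jointly by gradient descent on the class loss summed over
samples. Because the losses are linear-Gaussian residuals, the expression
MSE reported everywhere is proportional to a negative log-likelihood, and
models of the same class are directly comparable.

Two mixing modes are exposed. `linear` leaves $Z$ unconstrained, so
networks live in the archetype *span*; `simplex` passes the encoder output
through a softmax, making $\theta_n$ a convex combination. The span view is
the default since it is the weaker assumption; both are tested, and with
$K = 1$ the simplex mode degenerates to a single context-independent
network (a useful sanity contract).

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `K` | 16 | archetype count; an over-complete dictionary costs little because unused directions shrink, while the validation loss at larger `K` is never worse on heterogeneous data |
| `lambda` | 1e-3 | lasso weight per off-diagonal entry (dimensionless; the loss is mean-per-entry scaled so `lambda` is comparable across `n` and `p`) |
| `hidden_widths` | (64, 64) | encoder capacity; `integer(0)` gives a linear (varying-coefficient) encoder, useful because networks are then provably affine in context |
| `learning_rate` | 1e-3 | Adam step size; full-batch below 1024 samples, minibatches above |
| `val_fraction`, `patience` | 0.2, 10 | early stopping on the validation loss (computed without the penalty) |
| `mode` | linear | archetype span vs convex combination (see above) |

The sums in the written losses are reduced by the **mean** over all residual
terms ($np$ terms for neighborhood/Markov, $np^2$ for correlation), and the
penalty by the mean over the $p^2$ matrix entries. This makes losses
comparable across sample sizes and panels and makes reported MSEs
per-entry quantities; with unit-variance (z-scored) genes a trivial
all-zero network scores MSE $\approx 1$, a convenient absolute anchor.
Expression is z-scored per gene with training-split statistics; context
encodings (z-scores for continuous features, one-hot with an explicit NA
level for categoricals, mean imputation plus a missingness indicator) are
likewise frozen on the training split and reapplied verbatim at prediction
time.

## Optimization and numerical choices

Gradients are exact and hand-derived: the losses are quadratic in
$\theta_n$, mixing is bilinear in $(Z, A)$, and the encoder is ordinary
backpropagation with tanh hidden units (smooth, so the context-to-network
map is smooth, which matters for interpolating between sparsely sampled
contexts). The optimizer is Adam with bias correction. Archetypes are
initialized near zero so initial networks are approximately zero — early
training is then stable regardless of scale — and encoder weights use
small-variance Gaussian initialization. One master seed derives the
validation split, the initialization and the per-epoch shuffling through a
fixed counter scheme, so a fit is exactly reproducible and two fits with
the same seed write byte-identical model bundles.

Early stopping restores the best-validation iterate by default. That
iterate is implicitly shrunk relative to the loss optimum (it often beats
the converged solution on held-out data — the usual early-stopping
regularization effect). When the converged optimum itself is wanted, e.g.
to verify that the homogeneous-limit fit coincides with closed-form OLS,
`restore_best = FALSE` returns the final iterate instead.

The ℓ1 term uses the subgradient; gradient training therefore never
produces exact zeros, so neighborhood networks are reported dense and any
edge thresholding is a post-hoc, user-controlled step (default: none).
Squared correlations are not constrained to $[0,1]$ during training;
reconstruction clips them with a warning. For Markov networks the unit
diagonal is a convention, so parameter-recovery comparisons rescale both
the estimated and true precision matrices to unit diagonal first
(equivalently, they compare signed partial correlations), making the metric
independent of either side's diagonal convention; `parameter_mse(...,
normalize = FALSE)` compares raw entries.

Baselines (`fit_grouped()`) minimize the identical losses per group. With
`lambda = 0` they are solved in closed form — columnwise least squares for
neighborhood, per-pair ratios for correlation, and for the symmetric Markov
fit an exact least-squares solve over the $p(p-1)/2$ free entries of the
symmetric zero-diagonal matrix (the objective is quadratic in them, so no
iterative optimization is needed). Groups with fewer samples than genes are
flagged as degenerate (`n < p` warning) and solved with a rank-deficient
least squares in which unidentifiable coefficients are set to zero.

## The simulation benchmark

The context-varying Gaussian draws $C \sim \mathrm{Unif}[-1, 1]$ and
$X \sim \mathcal{N}(0, \Sigma(C))$ with
$\Sigma(C) = \bigl[\begin{smallmatrix}1 & C\\ C & 1\end{smallmatrix}\bigr]$,
the smallest model whose network genuinely varies with context and whose
true precision $\Omega(C) = (1-C^2)^{-1}\bigl[\begin{smallmatrix}1 & -C\\
-C & 1\end{smallmatrix}\bigr]$ is available in closed form. Contexts are
kept inside $|C| \le 0.99$ so the covariance stays well conditioned. The
scaling grid crosses the number of contexts (horizontal scaling: more
experimental conditions) with replicates per context (vertical scaling),
five replicate draws per cell, and scores each estimator by unit-diagonal
normalized parameter MSE. The structural identities — one context makes
grouped and population the same computation; grouped error is
non-increasing in replicates — are exact or hold within Monte-Carlo noise,
and the qualitative crossover emerges: grouped wins with few, deeply
sampled contexts; the contextualized estimator stays accurate down to one
sample per context once contexts number in the thousands.

## Planted cohorts and what passing tests show

`generate_planted_cohort()` emulates the statistical structure of a
heterogeneous clinical cohort: each subtype has a random sparse symmetric
precision matrix (diagonally loaded to condition number ≤ 100 and rescaled
to unit diagonal), expression drawn from the corresponding Gaussian,
context columns that carry the subtype signal with configurable amplitude
(`informativeness`, 0–1) alongside pure-noise features, and exponential
survival times with subtype-specific hazards under independent exponential
censoring (default rate ≈ 20% censored). It deliberately does *not*
emulate real cohorts' measurement noise structure, batch effects,
non-Gaussian marginals, or realistic clinical-covariate distributions — so
green tests demonstrate that the machinery recovers structure it is
pointed at, not that any biological claim transfers to a particular
dataset.

For the zero-shot (hold-out-group) evaluation the planted-archetype cohort
is the wrong instrument: its subtypes have independent random networks, so
an entirely unseen subtype's network is unpredictable from context by
construction. The hold-out checks therefore use context-band groups of the
context-varying Gaussian, where one smooth map $\theta(C)$ is shared by all
groups and generalizing to an unseen band is possible exactly when the
model has learned that map. One caveat worth knowing: if the held-out
band's true network happens to equal the population average (the center
band), the population baseline is already optimal there and the two models
tie; the contextualized advantage is specific to held-out groups whose
networks differ from the average.

## Subtype discovery

Per-sample networks are flattened (all off-diagonal entries for the
asymmetric neighborhood class; the upper triangle of the reconstructed
symmetric precision/correlation for the other two, to avoid
double-weighting), then clustered by Ward-linkage hierarchical clustering
on Euclidean distance. The cluster count is chosen by the best mean
silhouette over k = 2..10 (ties to the smallest k), or forced to match a
reference subtyping when one is supplied. Context features are ranked by
subtype-vs-rest two-sided Welch t-tests (the unequal-variance form, as the
robust default), taking each feature's minimum p over subtypes; no
multiple-testing correction is applied by default since the ranking, not
the significance threshold, is the output — a Benjamini–Hochberg option
exists. Survival stratification is quantified by the k-group log-rank test
and all pairwise log-rank tests (`survival::survdiff`), reporting the
multivariate and minimum-pairwise p-values with $-\log_{10}$ transforms.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use desk-scale sizes chosen so
every mechanism is exercised with comfortable statistical margins: the
homogeneous-limit oracle at $n = 1000$, $p = 5$; parameter recovery at
2000 contexts × 1 sample; the crossover cell at 2 contexts × 1000 samples;
hold-out evaluation at 600 samples; subtype discovery at 3 × 100 samples
with $p = 8$ and hazard rates (0.5, 2, 8); permutation nulls at 200–400
resamples. Full-cohort analyses (tens of thousands of samples, 50
metagenes) run with the same code paths.

## Known limitations

* The bilinear (encoder × archetype) parameterization is nonconvex;
  different seeds reach different but functionally similar optima.
  Bootstrap ensembling (`bootstrap_fit()`) is the recommended stabilizer.
* Gradient training never yields exactly sparse networks; sparsity is a
  reporting choice, not a model property.
* The unit-diagonal precision convention recovers partial correlations,
  not absolute precision scales; quantities that depend on
  $\mathrm{diag}(\Omega)$ are not identified.
* Encoder extrapolation far outside the training context hull is
  uncontrolled (tanh saturation keeps it bounded but not calibrated);
  zero-shot claims are for contexts within or near the training
  distribution.
* The correlation-class loss treats each ordered pair independently, so
  its per-sample MSE includes $p$ zero-residual self-regression terms;
  absolute MSEs are comparable within a class only.
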