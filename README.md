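# ctxnet

Sample-specific Gaussian graphical network inference from per-sample
metadata, for systems biologists who need one network *per sample* — not
one per cohort — from bulk expression cohorts whose regulatory structure
varies with tissue, genomic alterations, immune composition or any other
measured context.

## The model

Classical estimators of gene regulatory networks assume i.i.d. samples.
`ctxnet` instead learns a *contextualized* estimator: a context encoder
`f` (a small multilayer perceptron) maps each sample's context vector
`C ∈ R^d` to mixing weights over `K` learnable network archetypes
`A_1, …, A_K ∈ R^(p×p)`, giving that sample its own parameter matrix

    θ(C) = Σ_k f(C)_k A_k .

Three network classes share this parameterization through linear
regression losses on expression `X` (so MSE is proportional to a Gaussian
negative log-likelihood):

- **neighborhood selection** — `‖X − Xθ′‖² + λ Σᵢ‖θ′ᵢ‖₁`, diagonal masked
  (`θ′ = (1−I)⊙θ`);
- **Markov networks** — symmetric regression `θ = γ′ + γ′ᵀ`; the precision
  estimate is `Ω̂ = −(γ′ + γ′ᵀ)` with unit diagonal, and partial
  correlations are `ρᵢⱼ = −ωᵢⱼ/√(ωᵢᵢωⱼⱼ)`;
- **correlation networks** — per-ordered-pair univariate regressions with
  `ρ̂²ᵢⱼ = θᵢⱼθⱼᵢ`.

Encoder and archetypes are trained end to end by backpropagation (exact
hand-derived gradients, Adam, early stopping), so the model shares
statistical strength across *all* samples and emits networks even for
contexts never seen in training. The package also ships the classical
baselines fitted under identical losses (population / cohort /
context-clustered), a context-varying Gaussian simulation benchmark with
ground-truth precisions, expression-MSE evaluation with hold-out-group
cross-validation, bootstrap ensembling, and network-parameter subtype
discovery with log-rank survival stratification tests.

## Worked example

Simulate the context-varying Gaussian `C ~ Unif[−1,1]`,
`X ~ N(0, [[1,C],[C,1]])` — 1000 contexts, one sample each — and fit a
contextualized Markov network:

```r
library(ctxnet)

dat <- sample_cvg(cvg_spec(n_contexts = 1000, samples_per_context = 1, seed = 1))
fit <- contextualized_fit(dat$expression, dat$context,
                          network_class = "markov", K = 4, lambda = 0,
                          hidden_widths = c(16, 16), learning_rate = 5e-3,
                          max_epochs = 300, patience = 25, seed = 1)
fit
#> <ctxnet_fit> markov network, p = 2 genes, K = 4 archetypes (linear mixing)
#>   trained 46 epochs (best 21), val loss 0.69089, n = 800 (+200 val)
```

Every context gets its own precision matrix; the fitted off-diagonal
tracks the true value `−C`:

```r
prec <- network_precision(predict(fit, data.frame(context = c(-0.8, 0, 0.8))))
round(prec[1, , ], 2)   # C = -0.8        round(prec[3, , ], 2)   # C = 0.8
#>      g1   g2                            #>       g1    g2
#> g1 1.00 0.84                            #> g1  1.00 -0.88
#> g2 0.84 1.00                            #> g2 -0.88  1.00

parameter_mse(network_precision(predict(fit, dat$context)), dat$true_precision)
#> [1] 0.004421033
```

A parameter MSE of 0.0044 (on unit-diagonal-normalized precisions whose
entries span ±1) means the per-sample networks are essentially recovered
from *single* observations per context — the regime where per-group
estimation is impossible. Against the population baseline fitted under the
same loss:

```r
pop <- fit_grouped(dat$expression, scheme = "population", network_class = "markov")
mean(expression_mse(predict(fit, dat$context), standardize_like(fit, dat$expression)))
#> [1] 0.6988
mean(expression_mse(predict(pop, n = 1000), standardize_like(pop, dat$expression)))
#> [1] 0.9989
```

a 30% reduction in expression MSE, close to the oracle bound for this
simulation (`E[1 − C²] ≈ 2/3` versus 1 for any context-blind model).
Downstream, `subtype_report()` clusters per-sample networks (Ward
linkage, silhouette-selected k), ranks associated context features by
subtype-vs-rest t-tests and tests survival stratification with log-rank
statistics; `tidy()`, `glance()` and `autoplot()` methods cover each
result type.

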