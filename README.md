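# ssaft — hierarchical spike-and-slab AFT models for grouped survival data

`ssaft` fits Bayesian log-normal accelerated failure time (AFT) models to
survival data organised in groups — for example, patients from many cancer
types — where each group may carry a different subset of the covariates.
It is aimed at analysts who want group-specific survival models that still
**borrow strength across groups**, with an explicit include/exclude answer
for every (covariate, group) pair, and at multi-omics workflows where the
predictors are per-sample component scores extracted from low-rank modules
of a multi-source factorization.

## The model

For subject *j* of group *i*, with observed time `y*_ij` (an event time, or
a right-censoring time `y^c_ij`) and covariates `X_ijl` for `l ∈ S_i` (the
covariates available in group *i*):

    log y_ij  ~  Normal( β_0i + Σ_{l ∈ S_i} β_il X_ijl , σ² )

    β_0i | β̃_0, λ²_0      ~  Normal(β̃_0, λ²_0)
    β_il | γ_il, β̃_l, λ²_l ~  (1 − γ_il) Normal(0, z²) + γ_il Normal(β̃_l, λ²_l)
    γ_il | π_l             ~  Bernoulli(π_l),     π_l ~ Beta(1, 1)
    β̃_0 ~ Normal(0, 10²),  λ²_0 ~ Inverse-Gamma(1, 1)
    β̃_l ~ Normal(0, 1),    λ²_l ~ Inverse-Gamma(5, 1)
    σ²  ~ Inverse-Gamma(0.01, 0.01),   z² = 1/10000

Each coefficient is a two-component mixture: a near point mass at zero (the
*spike*) or a diffuse *slab* whose mean and variance are inferred from the
groups in which the covariate is included — so concordant groups sharpen
each other's estimates.  A covariate-level inclusion probability `π_l` ties
the indicators together across groups.  Censored outcomes are imputed from
their truncated-normal full conditional inside a Gibbs sampler (compiled
core, seeded and bit-reproducible).  The posterior inclusion probability
`γ̂_il` is the average of the indicator draws after burn-in and thinning.

Seven model variants of this framework (`hierarchical`, `null`, `full`,
`fixed_0.5`, `shared`, `joint`, `separate`) run through the same engine and
are compared by k-fold cross-validation of the log posterior predictive
likelihood.  A simulation harness reproduces a six-condition study of
selection accuracy (mean squared deviation between true indicators and
`γ̂`, "mean SSD") and predictive accuracy.

## Worked example

Three groups; `age` and `score1` measured everywhere, `score2` only in two
groups; true effects: `age` +0.5 in every group, `score1` inert, `score2`
−0.7 where available; 40% censoring.

```r
library(ssaft)
set.seed(7)
av <- matrix(c(TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE,
               TRUE, TRUE, FALSE),
             nrow = 3, dimnames = list(c("g1", "g2", "g3"),
                                       c("age", "score1", "score2")))
params <- list(beta = matrix(c(0.5, 0.5, 0.5, 0, 0, 0, -0.7, -0.7, NA),
                             3, 3, dimnames = dimnames(av)),
               beta0 = c(1.2, 0.8, 1.5), sigma2 = 1)
dat <- sim_dataset(params, av, n_per_group = 120, censor_frac = 0.4)

fit <- ssaft(dat, variant = "hierarchical",
             chain = ssaft_chain(iterations = 4000, burnin = 2000, thin = 4),
             seed = 1)
fit
#> Hierarchical spike-and-slab AFT fit (variant: hierarchical)
#>   360 subjects, 3 group(s), 3 covariate(s), M = 8 coefficient slots
#>   chain: 4000 iterations, burn-in 2000, thin 4 (500 retained draws)
#>   posterior mean error variance: 1.046
#>   covariate-group pairs with inclusion probability > 0.5: 5

head(summary(fit), 7)
#>   covariate group mean_effect   ci_lower    ci_upper incl_prob
#> 1       age    g2  0.43277328  0.2463066  0.62648776     1.000
#> 2       age    g3  0.52340684  0.3226712  0.73214518     1.000
#> 3    score2    g1 -0.76032890 -0.9647103 -0.56357791     1.000
#> 4    score2    g2 -0.51420737 -0.7293287 -0.27614778     1.000
#> 5       age    g1  0.48178112  0.2565287  0.69961675     0.998
#> 6    score1    g1 -0.01701350 -0.2320132  0.02206110     0.126
#> 7    score1    g2 -0.01272402 -0.1944681  0.01913895     0.094
```

The truly informative pairs are selected with probability ≈ 1 and carry
credible intervals around their true effects; the inert covariate's
inclusion probabilities sit near the spike.  Predictive comparison of
variants uses the cross-validated log posterior predictive likelihood
(higher is better):

```r
cv_logpred(dat, "hierarchical", k = 5,
           chain = ssaft_chain(2000, 1000, 4), seed = 2)
#> Cross-validated log posterior predictive likelihood (hierarchical, 5 folds)
#>   per fold: -126.237, -95.8121, -104.325, -104.801, -92.0642
#>   mean:     -104.648
```

Fitted objects support `print`, `summary`, `coef`, `predict`, `residuals`,
`simulate` and `plot` (trace / inclusion heatmap).  `filter_subjects()` and
`standardize_predictors()` prepare raw tables; `module_svd()`,
`component_scores()`, `select_components()` and `assemble_design()` turn
low-rank multi-source modules into the design; `run_study()` and
`compare_models()` drive the simulation study.  A thin command-line
wrapper lives in `inst/cli/ssaft-cli.R` (`fit` and `simulate` subcommands).

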