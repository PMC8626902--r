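# increg

Interpretable linear modelling of gene expression regulation from
heterogeneous candidate regulators, with incremental forward feature
selection under a shared cross-validation partition.

## The problem

In tumor cohorts, the expression of a target gene is shaped by several
kinds of regulators at once: methylation of its promoter, the activity of
genes in the same biological pathway, transcription factors (TFs) that bind
its promoters, and genes or TFs of other pathways of interest.  `increg`
organises these candidates, per target gene *g*, into five nested data
matrices over the cohort samples:

| level | adds |
|-------|------|
| M1 | own promoter methylation + expression of same-set genes |
| M2 | + expression of TFs binding any promoter of *g* |
| M3 | + expression of TFs binding promoters of any same-set gene |
| M4 | + expression of genes of the other sets |
| M5 | + expression of TFs of other-set genes |

Promoters are strand-aware windows of 2000 bases upstream / 1000 downstream
of each transcription start site; methylation is the mean beta value of the
probes in an extended window (4000 up / 1000 down), pooled over all TSSs of
the gene.  A TF is a candidate regulator of *g* when any of its ChIP-seq
peaks overlaps any promoter window of *g* by at least one base.

## The estimator

The matrices M2, M3, M5 are analysed in sequence by **incremental forward
feature selection with re-evaluation**.  At each step the candidate pool is
the new column group plus the consensus of the previous step, so features
selected earlier must compete again.  Within each of five shared
cross-validation folds, a greedy path is grown by adding, at each size, the
candidate whose OLS fit on the training samples maximizes R² on the
held-out fold; the fold's subset is the path prefix with maximal held-out
R², and only features chosen in **all five folds** form the step consensus.

The consensus features of each level are then fitted on all samples by
ordinary least squares after z-scoring every variable (mean 0, variance 1),
so coefficients are standardized effects:

    EXPR_g = c1*v_f1 + c2*v_f2 + ... + cn*v_fn + e

A feature is *significant* when the 95% t-based confidence interval of its
coefficient excludes 0.  Model quality is tracked by the adjusted R²
(`1 - (1-R²)(n-1)/(n-k-1)`) and, for strategy comparisons, the Gaussian BIC
(`n log(RSS/n) + (k+1) log n`).  Significant features define a signed,
weighted regulatory network (feature → target); fitted models can be
transferred unchanged to a second cohort and re-scored there.

Four alternative selection strategies (incremental without re-evaluation,
forward selection on all features, and lasso with/without the incremental
scheme) are included for benchmarking via `compare_selection()`.

## Worked example

A fully synthetic cohort with planted regulatory truth (400 samples, two
gene sets, 3 planted regulators per target, true R² 0.7) is generated,
written in the standard formats (GTF, narrowPeak, probe/expression TSVs,
GMT), read back and modelled:

```r
library(increg)

co  <- simulate_cohort(cohort_config(), seed = 1)
fit <- fit_cohort(co, seed = 0)

fit$fits[["A01"]]
#> <regfit: target A01, strategy incr_ffs_reeval>
#>   M2: k = 3, R^2 = 0.393, adj. R^2 = 0.389, BIC = -177.0
#>   M3: k = 3, R^2 = 0.546, adj. R^2 = 0.543, BIC = -293.0
#>   M5: k = 3, R^2 = 0.707, adj. R^2 = 0.705, BIC = -468.5

coef(fit$fits[["A01"]], level = "M5")
#>   (Intercept)      EXPR_BM1     EXPR_TF17      METH_A01
#> -1.554330e-17  4.767686e-01  4.605557e-01 -5.027013e-01
```

The three selected features are exactly the planted regulators of `A01`
(planted coefficients −0.524 for its own promoter methylation, +0.438 for
the TF, +0.483 for the other-set gene); the fitted standardized effects
match them closely, and the per-level R² climbs as each regulator's group
enters the analysis.  Across all 20 targets:

```r
net <- build_network(fit, level = "M5")
net
#> <reg_network [M5]: 51 nodes, 55 edges (30 repressing)>

score_recovery(fit, co$truth)[c("recall", "precision", "coef_rmse")]
#> recall 0.917  precision 1.000  coefficient RMSE 0.022
```

Networks export to SIF/TSV/GraphML (`export_network()`); models transfer to
a second cohort with `transfer_fit()`, which flags genes as similarly
regulated when the source adjusted R² is ≥ 0.4 and the two cohorts agree
within ±0.1.

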