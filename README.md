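# depthsurv

How much sequencing depth — and how many patients — does an RNA-seq
survival model actually need? Tumor profiling studies buy reads and
recruit patients under a budget, and past a saturation point neither
improves prediction. `depthsurv` finds that point for a cohort by
degrading the data *in silico* and measuring when prediction starts to
suffer. It is aimed at statisticians and bioinformaticians planning
sequencing studies with survival endpoints (and at anyone curious how
much of a deep cohort's budget was wasted).

## What it does

* **Binomial thinning.** Sequencing at a fraction ε of the original depth
  is equivalent to replacing each count R<sub>ij</sub> with a
  Binom(R<sub>ij</sub>, ε) draw; δ = 1/ε is the fold reduction
  (`thin_counts()`). The default grid is δ ∈ {1, 10, 100, 1000, 10000};
  training fractions x ∈ {10%, …, 80%} degrade cohort size with the test
  fold fixed at 20%.
* **Models.** Elastic-net Cox (Breslow partial likelihood, penalty
  λ(α‖β‖₁ + (1−α)/2‖β‖₂²) with α = 0.3, λ by internal cross-validation,
  Breslow baseline hazard) and a random survival forest (50 bootstrap
  trees, log-rank splitting, ≥3 patients per leaf, Nelson–Aalen leaf
  cumulative hazards, OOB-based mtry tuning).
* **Scoring.** Concordance index C = P(T_i < T_k | RS_i > RS_k) and the
  IPCW integrated Brier score, from 10 repetitions of 5-fold
  cross-validation (50 values per scenario), after TMM normalization,
  log₂-CPM, detection filtering (CPM > 1 in ≥ 1% of patients), a
  2500-gene univariate-Cox prescreen and train-anchored standardization.
* **Decision rule.** `max_fold_reduction()` reports the largest δ at
  which *neither* metric is degraded versus δ = 1 (paired one-sided
  Wilcoxon tests, BH-adjusted, level 0.05), requiring all smaller δ to
  pass as well. Companions: `inclusion_test()` (is the median C-index
  significantly above 0.6?), `hypothesis_decomposition()` (is depth loss
  about losing *genes* or losing *signal-to-noise*?), and
  `external_validation()` (train on thinned subsamples, test on a fixed
  external cohort).
* **Synthetic cohorts.** `simulate_cohort()` generates miRNA-seq- or
  mRNA-seq-like counts (log-normal library sizes and abundances,
  gamma-Poisson noise), Weibull proportional-hazards survival driven by a
  sparse set of prognostic genes, calibrated censoring and clinical
  covariates — the whole pipeline runs without downloading anything.

## Worked example

Plant six prognostic genes at relative abundance 10⁻³ in a 140-patient,
300-gene cohort sequenced at ~5×10⁶ reads — each prognostic gene carries
~5000 reads at full depth, so its signal should survive mild thinning and
drown around δ ≈ 100–1000:

```r
library(depthsurv)

cfg <- simulation_config(n_patients = 140, p_genes = 300, median_depth = 5e6,
                         n_prognostic = 6, effect_size = 0.8,
                         prognostic_abundance = 1e-3, target_censoring = 0.5,
                         seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> synthetic cohort: 300 genes x 140 patients
#>   median library size: 4.89e+06 reads
#>   events: 69 / 140 (censoring 0.51)
#>   prognostic genes: 6

grid <- saturation_grid(cohort$counts, cohort$survival,
                        scheme = cv_scheme(folds = 5, repetitions = 2, seed = 1),
                        deltas = c(1, 10, 100, 1000, 10000))
aggregate(value ~ metric + delta, grid, median)
#>    metric delta     value
#> 1  cindex     1 0.7764321
#> 2     ibs     1 0.1647944
#> 3  cindex    10 0.7986175
#> 4     ibs    10 0.1626742
#> 5  cindex   100 0.7587221
#> 6     ibs   100 0.1775125
#> 7  cindex  1000 0.5000000
#> 8     ibs  1000 0.2166813
#> 9  cindex 10000 0.5000000
#> 10    ibs 10000 0.2232493

max_fold_reduction(grid)
#> Maximum fold reduction without degraded prediction (cox, omics, x = 80%): 100
#> Metric degraded first: both
#>  delta  metric            p  p_adjusted
#>     10 C-index 0.8388671875 0.838867188
#>     10     IBS 0.4609375000 0.526785714
#>    100 C-index 0.2460937500 0.328125000
#>    100     IBS 0.0654296875 0.104687500
#>   1000 C-index 0.0009765625 0.001953125
#>  1000     IBS 0.0009765625 0.001953125
#>  10000 C-index 0.0009765625 0.001953125
#>  10000     IBS 0.0009765625 0.001953125
#> (p-values are indicative: CV samples share patients and are not independent)
```

Reading the output: the cross-validated C-index sits near 0.78 and is
statistically indistinguishable from full depth through δ = 100 (adjusted
p ≥ 0.10 for both metrics), then collapses to chance (C = 0.50) by
δ = 1000 — this cohort could have been sequenced at 1% of its depth
(~50,000 reads/patient) without losing prognostic power, but not at 0.1%.
`plot_saturation(grid)` draws the corresponding saturation curve, and the
same grid evaluated over `train_fractions` answers the cohort-size
question.

The methods vignette (`vignettes/depth-saturation-methods.Rmd`) documents
the models, the tie and weighting conventions, the decision rule, the
generator's assumptions and its limits.

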