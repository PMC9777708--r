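---
title: "Methods: sequencing-depth and cohort-size saturation for survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequencing-depth and cohort-size saturation for survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthsurv)
```

## The question

Designing a tumor-profiling study forces two budget decisions: how deeply to
sequence each sample, and how many patients to recruit. Both cost money, and
past some point neither improves a survival model. `depthsurv` quantifies
that saturation point for a given cohort: it degrades the data *in silico*
(fewer reads, fewer training patients), refits the models, and reports the
largest degradation that leaves prediction statistically intact.

## Degrading the data

**Depth.** Sequencing a library at a fraction $\varepsilon \in (0, 1]$ of its
depth is statistically equivalent to replacing each read count $R_{ij}$
(gene $j$, patient $i$) by a draw from $\mathrm{Binom}(R_{ij},
\varepsilon)$. `thin_counts()` implements exactly this; $\delta =
1/\varepsilon$ is the *fold reduction*. Binomial thinning composes
($\varepsilon_1$ then $\varepsilon_2$ equals $\varepsilon_1\varepsilon_2$),
and it maps a gamma-Poisson count to another gamma-Poisson count, which is
why the synthetic generator (below) uses that family. Thinning is applied to
the raw counts *before* normalization, and normalization is recomputed on
the thinned matrix: a shallow sequencing run would be normalized from its
own reads, so the degraded pathway must be too. Both the training and the
test half of each split are thinned (with independent seeds), mimicking a
world where the cheaper assay is used for everyone. The default grid is
$\delta \in \{1, 10, 100, 1000, 10000\}$.

**Cohort size.** The training fraction $x$ ranges over $10\%, \dots, 80\%$
of the cohort, drawn uniformly without replacement from the training pool of
each split; the test fold is always the untouched 20%.

## From counts to models

Each cross-validation split runs the same pipeline on its training fold:
TMM normalization factors (`tmm_factors()`, the canonical trimmed-mean
settings: 30% trim on M-values, 5% on A-values, precision weighting,
reference library chosen by the upper-quartile rule), voom-style log
expression $\log_2\!\big((r + 0.5) / (Lf + 1) \cdot 10^6\big)$
(`log_cpm()`), a detection filter (a gene is *detected* when its un-logged
CPM exceeds 1 in at least 1% of patients — boundary inclusive), a
univariate-Cox likelihood-ratio prescreen keeping the 2500 most
survival-associated genes, and per-gene standardization by the *training*
mean and SD. The test fold is projected through the training fold's gene
set and standardization; an external cohort on another measurement scale is
instead standardized by its own statistics.

Two deliberate choices are worth flagging because the alternatives are
defensible: the prescreen and the detection filter run *inside* each
training fold (never on the test fold) to avoid selection leakage into the
evaluation, and the detection filter participates in the modeling pathway
rather than being a reporting device only.

**Cox with elastic net.** The hazard model is $h(t \mid X_i) = h_0(t)
\exp(\beta^\top X_i)$ fitted by maximizing the Breslow partial likelihood
minus the penalty $\lambda(\alpha\lVert\beta\rVert_1 + \tfrac{1 -
\alpha}{2}\lVert\beta\rVert_2^2)$ with $\alpha = 0.3$. Fitting is
coordinate descent along a 100-point $\lambda$ path down to $0.01 \cdot
\lambda_{\max}$ (via glmnet, with standardization disabled — inputs arrive
standardized); $\lambda$ is chosen by internal 5-fold cross-validated
partial-likelihood deviance at its minimum ("lambda-min"; the
one-standard-error rule is exposed as an option). The baseline cumulative
hazard is the Breslow step function, giving survival curves $S(t \mid X) =
\exp(-H_0(t) e^{\beta^\top X})$. The risk score is the linear predictor.
Clinical covariates, when combined with an omics risk score, are refitted
*unpenalized* on the training fold ($RS = \beta \cdot RS_{\text{omics}} +
\sum_l \beta_l \mathrm{Clin}_l$) so a handful of clinical variables is not
diluted among thousands of penalized genes.

**Random survival forest.** 50 bootstrap trees; at each node `mtry`
($\lceil\sqrt{p}\rceil$ by default) features are sampled and every midpoint
between consecutive distinct values is scored by the two-sample log-rank
statistic; the split with the largest absolute statistic wins, with
deterministic tie-breaks (lowest feature index, then lowest threshold).
Nodes with fewer than 3 patients per child are not split. Each leaf stores
the Nelson–Aalen cumulative hazard of its bootstrap members on the global
grid of training event times, so the ensemble CHF is a plain average; the
risk score is the CHF averaged over that grid, and survival curves are
$\exp(-\mathrm{CHF})$. `tune_mtry()` minimizes out-of-bag error (1 − OOB
concordance) over $\{\lceil\sqrt p/2\rceil, \lceil\sqrt p\rceil, \lceil
2\sqrt p\rceil, \lceil p/3\rceil\}$; tuning is off by default inside the
benchmark loops (it quadruples the forest cost and rarely moves the
saturation conclusions) and can be switched on with `rsf_tune = TRUE`.

## Scoring

**C-index.** $C = P(T_i < T_k \mid RS_i > RS_k)$ estimated over comparable
pairs: the earlier time must be an observed event (or both patients fail at
the same time). Risk-score ties score 1/2; tied event times with both
events are counted but carry no ordering information, so they also score
1/2; an event tied with a censoring is not comparable.

**Integrated Brier score.** The Brier score at $t$ is the IPCW-weighted mean
of $\hat S(t)^2$ for patients who failed by $t$ (weight $1/G(T_i^-)$) and
$(1 - \hat S(t))^2$ for patients still at risk (weight $1/G(t)$), where $G$
is the Kaplan–Meier estimate of the *censoring* distribution computed on
the evaluation fold; patients censored before $t$ contribute nothing, and
patients whose weight would divide by $G = 0$ are excluded and counted. The
IBS is the trapezoidal integral over $\{0\} \cup \{\text{test event
times}\}$ up to the last test event time $\tau$, divided by $\tau$.

Ten repetitions of 5-fold cross-validation give 50 values of each metric
per scenario point, sharing the same split structure across all scenario
points so comparisons are paired.

## The decision rule

For each $\delta > 1$ (ascending), `max_fold_reduction()` runs paired
one-sided Wilcoxon tests against $\delta = 1$: degradation means a *lower*
C-index or a *higher* IBS. The depth is reducible by $\delta$ iff neither
metric is degraded at level 0.05 for $\delta$ *and* every smaller
reduction (monotone closure — the tables' single-breakpoint structure is
imposed rather than assumed). The decision uses Benjamini–Hochberg-adjusted
p-values within the comparison family: with four or more simultaneous
tests, a raw 0.05 per test would flag spurious degradation on null data
far more often than the nominal 5%. `"<1"` is reported when the smallest
tested reduction already degrades. Because the 50 CV values share patients,
all p-values are indicative rather than exact — they are labelled as such
in every printout. Note that pairing makes the tests sensitive to *any*
sign-consistent shift, however small: the reported maximum reduction marks
the onset of measurable attenuation, which can sit one grid step before
the fold reduction at which performance visibly collapses. That
conservatism is the appropriate default for a rule meant to tell a study
designer how much depth is safe to give up.

Related machinery: `inclusion_test()` implements the cohort-inclusion rule
(median C-index significantly above 0.6); `hypothesis_decomposition()`
separates the two candidate mechanisms of depth loss by comparing (A) full
data, (B) full depth restricted to the genes still detectable after extreme
thinning, and (C) the thinned version of (B) on shared splits — A ≈ B with
B > C indicates the loss is per-gene signal-to-noise, not gene detection;
`external_validation()` repeatedly trains on subsamples of the sequencing
cohort (thinned at each $\delta$) and scores a fixed, never-thinned
external cohort.

## The synthetic generator

Real TCGA-scale data cannot ship with a package, and the study design
questions do not require it: they require data with the right *structure*.
`simulate_cohort()` generates:

* **Counts.** Per-patient library sizes log-normal around `median_depth`
  (default $5 \times 10^6$ reads, miRNA-seq-like; an mRNA-seq-like cohort
  uses $\sim 5 \times 10^7$ over $\sim 2 \times 10^4$ genes), spread
  `depth_log_sd = 0.3`. Gene relative abundances log-normal with
  `abundance_log_sd = 2`, so a minority of genes dominates the reads as in
  real miRNA-seq. Counts are gamma-Poisson with per-gene dispersion 0.15 —
  the dispersion *is* the biological patient-to-patient variation, and it
  is what thinning progressively buries under Poisson noise.
* **Survival.** Weibull proportional hazards (shape 1.2, scale 5, arbitrary
  time units) on the linear predictor $\beta^\top X$ over `n_prognostic`
  genes with alternating signs and magnitude `effect_size` (log-hazard per
  SD of standardized log expression), optionally mixed with thresholded
  interaction terms (`nonlinear_fraction`) so the forest can out-predict
  the linear model on demand (default 0). Censoring is exponential with
  the rate calibrated by bisection to a target fraction (default 0.65,
  mid-range of typical TCGA cohorts, which span roughly 0.14–0.84); the
  generative mechanism of real-world censoring is unknown, so independence
  is an explicit assumption here.
* **Clinical covariates.** Age (normal, 60 ± 10), gender, grade, T, N, M
  with fixed realistic frequencies; optional log-hazard contributions via
  `clinical_effects`; `sex_specific` drops the gender column.
* **Placement controls.** `prognostic_quantile` plants the signal at a
  chosen abundance rank; `prognostic_abundance` pins the prognostic genes'
  relative abundance exactly — that is how the test suite builds cohorts
  whose signal dies between two specific fold reductions (at
  $10^{-3}$ relative abundance and $5 \times 10^6$ reads, a prognostic
  gene carries ~5000 reads at full depth, ~50 at $\delta = 100$, and ~0.5
  at $\delta = 10^4$). Planted designs keep the total
  linear-predictor variance moderate (a handful of genes at
  `effect_size` ≈ 0.8): piling many strong effects together inflates
  unexplained frailty, which attenuates every *marginal* gene–survival
  association and makes planted signal paradoxically harder for a fitted
  model to find, even when an oracle using the true coefficients still
  discriminates well.

One seed expands into per-stage substreams (abundances, counts, clinical,
survival, censoring), so identical configurations are bit-reproducible and
stages can be re-randomized independently. What the generator does *not*
emulate: batch effects, cancer-specific co-expression structure, mutation
landscapes, or informative censoring. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the stated generative
assumptions, not that any particular real cancer saturates at a particular
depth.

## Numerical choices and degenerate inputs

* Elastic-net convergence: coordinate-descent tolerance $10^{-7}$, at most
  $10^5$ sweeps; both configurable. KKT conditions of the stated objective
  are verified in the test suite at tolerance $10^{-6}$.
* Genes with zero training variance are dropped from both folds and
  reported; constant covariates in a univariate Cox test return p = 1 with
  a warning; patients with zero library size get TMM factor 1 with a
  warning.
* CV folds are redrawn (up to 20 times) when a fold would leave fewer than
  2 training events or an event-free test fold; all-zero Wilcoxon
  differences return p = 1; a forest on an all-censored cohort refuses to
  fit.
* Log-rank variance uses the hypergeometric form with $n_k = 1$ risk sets
  skipped; zero-variance splits score 0 and are never chosen.
* Times beyond a model's training horizon get flat-extrapolated survival
  curves, flagged via an attribute.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at deliberately modest sizes —
cohorts of 100–400 patients, 100–300 genes, 2–10 CV repetitions, 10–20
generator seeds per property — which keep the whole suite within a coffee
break while leaving every qualitative conclusion (null calibration, planted
breakpoint recovery, detection-vs-noise decomposition, support recovery)
intact. The same functions run unchanged at TCGA scale; only the grids and
repetition counts grow.

## Known limitations

* The Wilcoxon machinery treats the 50 CV values as a sample; they are
  positively dependent, so the tests' levels are nominal only (hence
  "indicative" everywhere).
* Efron tie handling, stratified or time-varying Cox models, alternative
  splitting rules and variable-importance measures are out of scope.
* The generator's independence assumptions (genes, censoring) are stronger
  than reality; planted-signal recovery rates on synthetic data are upper
  bounds on what correlated real data would give.
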