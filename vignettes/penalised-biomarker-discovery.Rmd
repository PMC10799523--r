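---
title: "Penalised biomarker discovery for sepsis mortality and endothelial damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalised biomarker discovery for sepsis mortality and endothelial damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolasso)
```

`metabolasso` links a small ICU cohort's plasma metabolome to 30-day
mortality and to two endothelial damage markers (PECAM and soluble
thrombomodulin) through sparse penalised regression, and carries the whole
supporting chain: preprocessing, cohort statistics, penalty selection, ROC
comparison, pathway enrichment and cross-model overlap. This vignette is
the package's account of the methods: the models and their assumptions, the
parameters that matter, the numerical choices, what the synthetic cohort
does and does not emulate, and the known limitations.

## The penalised regression core

For a response $y$ (a 0/1 death indicator or a continuous marker
concentration) and $p$ predictors, coefficients minimise

$$\mathrm{Cost}(w) \;=\; \frac{1}{2N}\sum_{i=1}^{N}\Big(y_i -
\sum_{j=1}^{p} w_j x_{ij}\Big)^2 \;+\; \lambda \sum_{j=1}^{p} v_j\,|w_j|,$$

with a per-predictor penalty vector $v$ (all 1 by default; a $v_j$ of 0
leaves predictor $j$ unpenalised). Design columns are centred and scaled to
unit sample variance and $y$ is centred, so the unpenalised intercept is
$\bar y$ and coefficients are reported on the standardised scale;
`coef_raw_scale()` maps them back.

Three modelling assumptions deserve emphasis:

* **Squared-error loss for all responses, including the binary one.** The
  objective above is squared error, and the selection machinery scores
  models by cross-validated MSE throughout, also for the death indicator.
  This treats the binary outcome as a linear-probability problem; it keeps
  one objective for all three responses and one selection criterion. An
  L1-penalised logistic variant (`lasso_fit_logistic()`, majorised
  coordinate descent) is provided for users who prefer a binomial link, but
  it is not the default and the pipeline does not use it.
* **No intercept penalty.** Centring handles the intercept implicitly; the
  penalty never touches it.
* **Unit penalty vector.** $v_j = 1$ for every predictor in the pipeline;
  the vector exists so that sensitivity analyses (e.g. shielding a clinical
  covariate from shrinkage with $v_j = 0$) need no new machinery.

The solver is cyclic coordinate descent with exact one-dimensional updates
$w_j \leftarrow S\big((1/N)\,x_j^\top r_{-j},\ \lambda v_j\big) / (x_j^\top
x_j / N)$, where $S$ is the soft-threshold operator, implemented in C++
with in-place residual updates. Each step is an exact coordinate minimiser,
so the objective is non-increasing; iteration stops when the largest
coefficient change in a sweep falls below `tol` (default `1e-7`, well below
the noise floor of anything reported) or after `max_sweeps` (default
`1e4`). Solutions are certified by the KKT conditions (`kkt_residuals()`):
the tests require residuals below `1e-6` and agreement with an independent
proximal-gradient solver and with `glmnet` to `1e-5`. At or above
`lambda_max()` $= \max_j |x_j^\top y|/(N v_j)$ the fitted vector is exactly
zero. Warm-started paths over a decreasing grid (`lasso_path()`) match
cold starts to `1e-6`.

Degenerate inputs: constant (zero-variance) columns are centred, flagged
internally, and can never enter the model; non-finite values are rejected
before fitting; $\lambda < 0$ errors.

## Penalty selection: bootstrap-median cross-validation

A single 5-fold split at $n \approx 50$ selects a noisy $\lambda$. The
pipeline therefore draws $B$ bootstrap resamples of patients; inside each,
a seeded 5-fold cross-validation scores a log-spaced grid (default 100
points from $\lambda_{\max}$ down to $10^{-3}\lambda_{\max}$) by held-out
MSE, with standardisation parameters recomputed on each training split and
applied to its held-out fold (no leakage). The per-resample optimum is the
CV-MSE argmin, with ties broken toward the larger (sparser) $\lambda$; the
selected penalty is the median of the $B$ optima (even $B$: mean of the
central pair), and the final model is refit on all patients at that value.
Resamples whose response has zero variance (possible for a binary outcome)
are redrawn with a bounded retry count and logged.

Numerical choices worth recording: the grid is computed once from the full
data so per-resample optima live on a common scale; CV fold fits use a
looser solver tolerance (`1e-4`, capped at 1000 sweeps) because held-out
MSE is flat far below that precision while near-zero penalties on
ill-conditioned $p \gtrsim n$ resamples converge slowly — the final fit
always uses the tight `1e-7`. $B$ and the grid size are configuration:
the full profile is $B = 500$ with a 100-point grid; the reduced profile
($B = 25$, 40 points) is the default for interactive runs and testing, and
on the synthetic cohort the two agree to within a grid step. The stability
tests run $B = 100$ across ten master seeds on a fixed problem and require
the interquartile range of the selected $\log\lambda$ to stay below half a
grid step.

The predictor roster for each response is the scaled metabolite matrix plus
the clinical variables significant (p < 0.05) in the survivor/non-survivor
comparison, minus the response itself. No leakage exclusion beyond that is
attempted (e.g. SOFA components when modelling mortality); the roster is
config-driven (`clinical_covariates`) and logged, so any exclusion policy
can be imposed explicitly.

## Preprocessing

The chain runs in a fixed order: (1) drop features missing in **strictly
more than** 10 % of patients; (2) drop patients missing strictly more than
10 % of retained features; (3) drop any feature containing a nonpositive
observed value — nonpositive concentrations signal failed quantification,
and the whole feature is removed rather than clipping cells; (4) impute;
(5) natural log; (6) Pareto scale. Both thresholds use strict inequality
(a feature missing in exactly 10 % of patients is retained), and the
filters are idempotent.

Imputation default is chained random-forest with predictive-mean matching:
each incomplete feature is regressed on all others with a `ranger` forest,
missing entries take the observed value of a donor drawn from the
`pmm_k = 3` nearest out-of-bag predictions, and the sweep repeats until the
mean out-of-bag error stops improving (cap 10 iterations). PMM guarantees
imputed values are actual observed concentrations (hence positive, so step
5 is safe). `knn` and `median` imputers are provided as fast deterministic
alternatives; all three leave observed cells bit-identical and are
deterministic under `imputation_seed`. Pareto scaling is
$(z - \bar z)/\sqrt{s_z}$ on the log values with the $n-1$ sample SD; each
scaled feature has mean 0 and variance equal to the SD of its logs —
damping, not erasing, variance differences. The transform is invertible
(`unscale_log_pareto()`, round-trip within `1e-10`), the log base is
recorded in the report, and only metabolites are transformed: clinical
covariates pass through untouched and enter the regressions on their raw
scale (the problem constructor standardises every design column anyway).

## Cohort statistics

Discrete variables use Fisher's exact test; the two-sided 2×2 p-value
follows the minimum-likelihood rule (sum of hypergeometric point
probabilities no larger than the observed table's), which is what
reproduces the published worked examples (sex table p = 1.000, septic-shock
table p = 0.391). General r×c tables with total count ≤ 200 are enumerated
exactly; larger tables fall back to a seeded Monte-Carlo p with a reported
standard error. Continuous variables use the Mann–Whitney U test: exact by
enumeration when the pooled sample is ≤ 20 without ties, otherwise the
normal approximation with tie and continuity corrections; identical
samples are flagged degenerate with $U = n_a n_b/2$, $p = 1$. Summaries are
median and lower/upper quartile under the type-7 (linear interpolation)
convention, fixed so tables are deterministic. Missing values are dropped
per feature by default; a flag turns them into their own discrete category,
since published tables are ambiguous on this point. No multiplicity
adjustment is applied across table rows (raw p-values are reported, as is
conventional for cohort description tables).

## ROC evaluation

AUC is the tie-aware concordance probability — concordant case/control
pairs plus half the ties over $n_+ n_-$ — computed from midranks; it equals
the trapezoidal area under the empirical curve and satisfies
$\mathrm{AUC}\cdot n_+ n_- = U$ exactly, which the tests assert against the
Mann–Whitney module on shared fixtures. Model scores are in-sample fitted
values of unpenalised least squares (minimum-norm with a warning when the
design is collinear), matching a fit-on-everything convention appropriate
to $n \approx 50$ — and documented as optimistic. `cv_auc()` provides the
honest out-of-fold counterpart, and the stage-5 driver prints both.
Confidence intervals default to DeLong structural components (normal
theory, clipped to $[0,1]$; degenerate $[\hat A,\hat A]$ with a warning
under perfect separation) with a seeded stratified bootstrap
(B = 2000, percentile) as the alternative.

## Over-representation analysis

Pathway sets enter as GMT files. The published analysis ran against a KEGG
pathway snapshot of a chemical-interaction database; those counts depend on
the database version, so the package does not try to reproduce them —
the bundled `synthetic_pathways.gmt` is a synthetic collection (so named)
over the generator's metabolite roster, and users supply their own
KEGG-derived GMT for real data. For each pathway with at least `min_size`
(default 2) members in the universe, the raw p is the upper-tail
hypergeometric probability of the observed overlap; the enrichment score is
$-\log_{10}(p)$, with Benjamini–Hochberg adjustment reported separately
(a pathway can have a large score and a modest adjusted p). The universe is
all measured, mappable metabolites — not just selected ones. The selection
rule is the final fit's support (nonzero coefficients); a `top_k` by
absolute coefficient is exposed because "selected by coefficient size" is
ambiguous between the two readings. Names are matched case-insensitively
after punctuation normalisation, with an optional synonym map, because
published rosters mix spellings ("Trimethyl N oxide" vs TMAO).

## The synthetic cohort

`cohort_spec()` defaults encode the cohort structure the pipeline was
designed around: 52 ICU sepsis patients, 63 quantified plasma metabolites,
19 deaths within 30 days, and 13 metabolites forced above the 10 %
missingness threshold. Log-concentrations are multivariate normal with
exchangeable correlation $\rho = 0.2$ (log-normality is the natural choice
given that the analysis log-transforms; the real covariance is
uncharacterised, so an exchangeable default is a convention, not a data
fact). PECAM and sTM are linear in the centred log-concentrations plus
Gaussian noise (default SD 1.5 ng/mL against marker means of 15–17);
mortality follows a logistic link by default (a linear-probability option
exists, matching the squared-error loss), with the intercept calibrated so
the expected death count is exact and draws rejected until exactly
`n_deaths` occur. The planted coefficient defaults overlap across the three
responses — histidine and urate positive everywhere, sphingosine
1-phosphate negative everywhere — so the overlap-reporting stage has
structure to find. Missingness is MCAR by default with a
concentration-dependent (MAR) option, since the real mechanism is unknown;
features carrying planted effects are exempt from the *forced*
high-missingness set, because reported biomarkers are by construction ones
that survived QC. The severity score is coupled to the mortality signal
only moderately (in-sample AUC ≈ 0.8), like a real ICU severity score
rather than an oracle.

What the generator does **not** emulate: instrument batch and drift
effects, internal-standard normalisation chemistry, censoring or
competing risks in the outcome, realistic metabolite-specific missingness,
or heavy-tailed concentration errors. Passing tests on synthetic cohorts
therefore demonstrate that the machinery is correct and that the procedure
recovers planted sparse signal under its own assumptions — not that the
selected panel would replicate in a new patient cohort.

## Recovery behaviour and limitations

The recovery suite plants four standardised effects of magnitude 1 in
$n = 100$, $p = 20$, noise SD 0.5, and requires the bootstrap-median final
fit ($B = 50$, 40-point grid) to contain the true support with correct
signs in at least 80 % of 20 replicates; in practice it recovers
essentially always at these settings. At the cohort's own scale
($n \approx 50$, $p \approx 50$, weaker effects) selection is visibly
noisier: individual runs of the stage drivers recover the planted shared
metabolites in most but not all realisations, and the in-sample AUC of the
selected model is optimistic (the cross-validated AUC printed beside it is
the honest number). These are properties of small-$n$ L1 selection itself,
worth keeping in mind when reading any single cohort's selected panel.

Problem sizes in the tests and the acceptance script (reduced $B$, 40-point
grids, 20 replicates) were chosen as the smallest sizes at which the
selection distributions stabilise; the full profile ($B = 500$, 100-point
grid) is one flag away in the stage drivers and the pipeline config.

Reproducibility: one master seed feeds a stage-name-keyed derivation
(`derive_seed()`), so any stage can be rerun in isolation and byte-identical
artifacts are a tested property of the pipeline. All randomness is
restored-state local: package functions never perturb the caller's RNG.
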