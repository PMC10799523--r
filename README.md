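# metabolasso

Sepsis kills a large fraction of the ICU patients it touches, and the
bedside severity stratifiers (septic-shock status, the SOFA score) say
little about *why* a given patient is at risk. Plasma metabolites offer both
prognosis and mechanism: if the metabolites that predict 30-day mortality
also track circulating markers of endothelial damage — PECAM (CD31, shed
when inter-endothelial junctions disassemble) and soluble thrombomodulin
(sTM, shed on direct endothelial injury) — the shared panel points at the
vascular biology behind the deaths.

`metabolasso` implements that analysis as a reusable, tested R pipeline:
sparse penalised regression links a patient × metabolite concentration
matrix to 30-day mortality and to the two endothelial markers, with the
full preprocessing, cohort-statistics, ROC-comparison, pathway-enrichment
and cross-model-overlap chain around it. A seeded synthetic-cohort
generator with planted ground truth makes every stage exercisable end to
end — no external data or network access required.

## The model

For response *y* (30-day death indicator, PECAM, or sTM) over *p*
standardised predictors, coefficients minimise the penalised least-squares
objective

    Cost(w) = (1/2N) Σᵢ ( yᵢ − Σⱼ wⱼ xᵢⱼ )² + λ Σⱼ vⱼ |wⱼ|

where `v` is a per-predictor penalty vector (all 1 by default) and λ ≥ 0
sets the sparsity/fit trade-off. The solver is cyclic coordinate descent
with exact soft-threshold updates (compiled core, KKT-verified solutions).
Because a single cross-validation split is unstable at n ≈ 50, λ is chosen
by a bootstrap-median procedure: B patient-resamples, each scored by 5-fold
cross-validated MSE over a log-spaced λ grid; the median of the B
per-resample optima is used for a final fit on all patients, whose nonzero
coefficients are the selected biomarkers.

Around the core: features missing in > 10 % of patients are dropped (then
patients missing > 10 % of features, then features with nonpositive
values), remaining holes are filled by chained random-forest imputation
with predictive-mean matching, and concentrations are log-transformed and
Pareto-scaled. Survivors and non-survivors are compared with Fisher's exact
test (discrete) and the Mann–Whitney U test (continuous); candidate
mortality predictors are compared by ROC/AUC with DeLong or bootstrap
confidence intervals; selected metabolites are tested against pathway sets
(GMT format) with an upper-tail hypergeometric test, −log10 score and
Benjamini–Hochberg adjustment; and the three model supports are partitioned
by sign and intersected Venn-style.

## Worked example

The `analysis/` directory holds the numbered stage drivers
(`01_simulate_cohort.R` … `06_ora_and_overlap.R`); run them in order from
the repository root. Stage 4/5 output on the default synthetic cohort
(52 patients, 63 metabolites, 19 deaths, master seed 1):

```
death30  median lambda 0.04529, support 15 (of 53 predictors)
pecam    median lambda 0.05671, support 31 (of 52 predictors)
stm      median lambda 0.07044, support 31 (of 52 predictors)

septic_shock           AUC 0.505 (95% CI 0.359-0.651)
sofa                   AUC 0.842 (95% CI 0.730-0.953)
pecam_stm              AUC 0.813 (95% CI 0.699-0.928)
metabolite_model       AUC 0.938 (95% CI 0.875-1.000)
metabolite model, 5-fold cross-validated AUC: 0.838
```

Read: the septic-shock flag is barely better than chance, SOFA and the
two endothelial markers are good (AUC ≈ 0.8), and the 15-metabolite
penalised model is best — optimistically so in-sample (0.94), which is why
the honest cross-validated counterpart (0.84) is printed next to it. Stage
6 then reports which metabolites share a sign across all three models (the
generator plants histidine/urate positive and sphingosine 1-phosphate
negative everywhere) and, as a worked example on the published 52-patient
coefficient roster shipped in `inst/extdata/reported_coefficients.csv`,
recovers the reported supports (mortality 15 = 9+/6−, PECAM 10+/13−, sTM
9+/6−) and the shared metabolites {histidine, urate} / {sphingosine
1-phosphate}.

The same machinery is available programmatically:

```r
library(metabolasso)
cfg <- pipeline_config(cohort = cohort_spec(seed = 42),
                       gmt = system.file("extdata", "synthetic_pathways.gmt",
                                         package = "metabolasso"),
                       seed = 1, out_dir = "results/run")
res <- run_pipeline(cfg)
print(res)
```

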