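#!/usr/bin/env Rscript
# Stage 1 — simulate the study-structured cohort.
#
# Generates the default synthetic sepsis cohort (52 ICU patients, 63
# quantified plasma metabolites, 19 deaths within 30 days, 13 metabolites
# pushed above the 10% missingness threshold) with planted sparse effects on
# mortality and on the two endothelial damage markers, and writes it as CSV
# under results/cohort/. Ground truth is kept in truth.json for the recovery
# checks in later stages.

suppressPackageStartupMessages(library(metabolasso))

master_seed <- 1L
spec <- cohort_spec(seed = derive_seed(master_seed, "cohort"))
cohort <- make_cohort(spec)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

print(cohort)
cat(sprintf("missing cells: %d (%.1f%%); features over the 10%% threshold: %d\n",
            sum(is.na(cohort$metabolites)),
            100 * mean(is.na(cohort$metabolites)),
            sum(colMeans(is.na(cohort$metabolites)) > 0.10)))
cat("written to results/cohort/\n")
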