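#!/usr/bin/env Rscript
# Stage 2 — filtering, imputation and scaling.
#
# Applies the fixed preprocessing order: features missing in > 10% of
# patients are dropped, then patients missing > 10% of retained features,
# then features with nonpositive observed values; remaining holes are filled
# by chained random-forest imputation with predictive-mean matching; finally
# the concentrations are log-transformed and Pareto scaled. The scaled
# matrix feeds every downstream model.

suppressPackageStartupMessages(library(metabolasso))

master_seed <- 1L
cohort <- read_cohort("results/cohort/metabolites.csv",
                      "results/cohort/clinical.csv")

cfg <- preprocess_config(imputation_seed = derive_seed(master_seed, "impute"))
pp <- preprocess(cohort, cfg)

print(pp$report)
write_preprocess_report(pp$report, "results/preprocess_report.json")
write.csv(data.frame(patient_id = rownames(pp$matrix), pp$matrix,
                     check.names = FALSE),
          "results/scaled_metabolites.csv", row.names = FALSE)
saveRDS(pp, "results/preprocessed.rds")
cat("scaled matrix and report written under results/\n")
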