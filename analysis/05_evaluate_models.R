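#!/usr/bin/env Rscript
# Stage 5 — ROC comparison of the candidate mortality predictors.
#
# Compares, on the same cohort and in-sample (all observations used for
# fitting, as appropriate for n ~ 50 and documented as optimistic): the
# septic-shock flag, the SOFA score, the unpenalised PECAM + sTM linear
# model, the penalised metabolite model, and the two metabolites with the
# largest absolute coefficients. DeLong 95% intervals throughout; a
# cross-validated AUC for the metabolite model is printed as the honest
# counterpart of the in-sample number.

suppressPackageStartupMessages(library(metabolasso))

master_seed <- 1L
pp <- readRDS("results/preprocessed.rds")
mod <- readRDS("results/models.rds")
clin <- pp$clinical
dat <- cbind(clin, as.data.frame(pp$matrix))
y <- clin$death30

scores <- list(
  septic_shock = linear_score(dat, "death30", "septic_shock"),
  sofa = linear_score(dat, "death30", "sofa"),
  pecam_stm = linear_score(dat, "death30", c("pecam", "stm")),
  metabolite_model = as.numeric(mod$problems$death30$X %*%
                                  mod$fits$death30$w) +
    mod$fits$death30$intercept)
w_met <- mod$fits$death30$w[intersect(names(mod$fits$death30$w),
                                      colnames(pp$matrix))]
for (m in select_features(w_met, rule = "top_k", k = 2))
  scores[[paste0("single_", m)]] <- linear_score(dat, "death30", m)

rocs <- list(); summary <- list()
for (m in names(scores)) {
  r <- roc_auc(scores[[m]], y)
  ci <- auc_ci(scores[[m]], y, method = "delong")
  cat(sprintf("%-22s AUC %.3f (95%% CI %.3f-%.3f)\n", m, r$auc, ci$low,
              ci$high))
  rocs[[m]] <- r
  summary[[m]] <- list(auc = r$auc, ci_low = ci$low, ci_high = ci$high)
}
cv <- cv_auc(dat, "death30",
             names(mod$fits$death30$w)[mod$fits$death30$w != 0],
             k = 5, seed = derive_seed(master_seed, "cv_auc"))
cat(sprintf("metabolite model, 5-fold cross-validated AUC: %.3f\n", cv$auc))
summary$metabolite_model_cv <- list(auc = cv$auc)

jsonlite::write_json(summary, "results/roc_summary.json", auto_unbox = TRUE,
                     digits = NA)
if (requireNamespace("ggplot2", quietly = TRUE))
  ggplot2::ggsave("results/roc_overlay.png", plot_roc_overlay(rocs),
                  width = 6, height = 4.5)
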