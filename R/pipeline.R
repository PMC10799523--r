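# End-to-end orchestration: (synthesise|load) -> preprocess -> cohort table
# -> per-response penalty tuning + final fit -> ROC comparison -> ORA ->
# cross-model overlap, with every artifact written under an output directory
# and a manifest recording the config hash and seeds. One master seed feeds a
# stage-name-keyed derivation (see derive_seed()) so each stage is
# independently reproducible.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to existing cohort CSVs) or `cohort`
#' (a [cohort_spec()] to synthesise) must be given; the master `seed` is
#' mandatory.
#'
#' @param cohort a [cohort_spec()], or `NULL` when loading real data.
#' @param input `list(metabolites = path, clinical = path)`, or `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param responses response columns to model (default mortality and the two
#'   endothelial markers).
#' @param clinical_covariates `"significant"` (clinical variables with
#'   comparison-table p < 0.05 join the predictor roster, the default),
#'   `"none"`, or an explicit character vector of clinical columns.
#' @param B,k,grid_size,grid_ratio penalty-tuning parameters; the reduced
#'   defaults (B = 25, grid 40) keep interactive runs fast. `profile =
#'   "full"` switches to B = 500, grid 100.
#' @param profile `"reduced"` (default) or `"full"`.
#' @param gmt optional path to a GMT pathway file for ORA.
#' @param ora_rule,ora_top_k,ora_min_size ORA selection settings.
#' @param seed master seed (mandatory).
#' @param out_dir output directory.
#' @param write_plots write diagnostic plots when ggplot2 is installed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input = NULL,
                            preprocess = preprocess_config(),
                            responses = c("death30", "pecam", "stm"),
                            clinical_covariates = "significant",
                            B = 25L, k = 5L, grid_size = 40L,
                            grid_ratio = 0.001,
                            profile = c("reduced", "full"),
                            gmt = NULL, ora_rule = "nonzero",
                            ora_top_k = NULL, ora_min_size = 2L,
                            seed, out_dir = tempfile("pipeline")) {
  if (missing(seed)) abort_fmt("a master seed is mandatory")
  profile <- match.arg(profile)
  if (profile == "full") { B <- 500L; grid_size <- 100L }
  if (is.null(cohort) == is.null(input))
    abort_fmt("exactly one of `cohort` (spec) or `input` (paths) must be given")
  if (!is.null(input) &&
      !all(c("metabolites", "clinical") %in% names(input)))
    abort_fmt("`input` needs elements `metabolites` and `clinical`")
  structure(list(cohort = cohort, input = input, preprocess = preprocess,
                 responses = responses,
                 clinical_covariates = clinical_covariates,
                 B = as.integer(B), k = as.integer(k),
                 grid_size = as.integer(grid_size), grid_ratio = grid_ratio,
                 profile = profile, gmt = gmt, ora_rule = ora_rule,
                 ora_top_k = ora_top_k, ora_min_size = as.integer(ora_min_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes the artifacts (cohort CSVs,
#' preprocessing report, comparison table, penalty searches, fits, ROC
#' summaries, ORA tables, overlap summary, manifest) under
#' `config$out_dir`. All randomness derives from the master seed via
#' [derive_seed()], so the same config and seed give identical results.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # -- stage 1: cohort ------------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- make_cohort(config$cohort)
    write_cohort(cohort, file.path(out, "cohort"))
  } else {
    cohort <- read_cohort(config$input$metabolites, config$input$clinical)
  }
  validate_pipeline_inputs(cohort, config)

  # -- stage 2: preprocessing ----------------------------------------------
  pp_cfg <- config$preprocess
  pp_cfg$imputation_seed <- derive_seed(config$seed, "impute")
  pp <- preprocess(cohort, pp_cfg)
  write_preprocess_report(pp$report, file.path(out, "preprocess_report.json"))

  # -- stage 3: cohort comparison table ------------------------------------
  stats_features <- setdiff(names(pp$clinical),
                            c("patient_id", "survival30", "death30"))
  comparison <- compare_groups(pp$clinical, "death30",
                               features = stats_features)
  write.csv(comparison, file.path(out, "comparison_table.csv"),
            row.names = FALSE)

  # predictor roster: retained metabolites + significant clinical covariates
  covars <- select_clinical_covariates(config, comparison, pp$clinical)

  # -- stage 4: penalty tuning + final fit per response --------------------
  fits <- list(); searches <- list(); problems <- list()
  for (resp in config$responses) {
    use_cov <- setdiff(covars, resp)
    design <- cbind(pp$matrix,
                    as.matrix(pp$clinical[, use_cov, drop = FALSE]))
    prob <- penalized_problem(design, pp$clinical[[resp]])
    search <- bootstrap_median_lambda(
      prob, B = config$B, k = config$k, grid_size = config$grid_size,
      grid_ratio = config$grid_ratio,
      seed = derive_seed(config$seed, paste0("tuning:", resp)))
    fit <- final_fit(prob, search$median_lambda)
    problems[[resp]] <- prob; searches[[resp]] <- search; fits[[resp]] <- fit
    write_lambda_search(search,
                        file.path(out, sprintf("lambda_search_%s.json", resp)))
    jsonlite::write_json(
      list(response = resp, lambda = fit$lambda,
           intercept = fit$intercept,
           coefficients = as.list(fit$w[fit$w != 0])),
      file.path(out, sprintf("fit_%s.json", resp)),
      auto_unbox = TRUE, digits = NA)
  }

  # -- stage 5: ROC comparison for mortality -------------------------------
  rocs <- evaluate_mortality_models(pp, fits, problems, config)
  jsonlite::write_json(
    lapply(rocs, function(r)
      list(auc = r$roc$auc, ci_low = r$ci$low, ci_high = r$ci$high,
           n_pos = r$roc$n_pos, n_neg = r$roc$n_neg)),
    file.path(out, "roc_summary.json"), auto_unbox = TRUE, digits = NA)

  # -- stage 6: ORA per response -------------------------------------------
  ora <- NULL
  if (!is.null(config$gmt)) {
    pw <- read_gmt(config$gmt)
    ora <- lapply(fits, function(f) {
      sel <- select_features(f, rule = config$ora_rule, k = config$ora_top_k)
      sel <- intersect(normalize_feature_name(sel), pw$universe)
      univ <- union(pw$universe,
                    normalize_feature_name(names(f$w)))
      ora_test(sel, pw, universe = univ, min_size = config$ora_min_size)
    })
    for (resp in names(ora))
      write.csv(ora[[resp]],
                file.path(out, sprintf("ora_%s.csv", resp)),
                row.names = FALSE)
  }

  # -- stage 7: cross-model overlap ----------------------------------------
  supports <- lapply(names(fits), function(m) sign_partition(fits[[m]], m))
  overlap <- overlap_summary(supports)
  jsonlite::write_json(overlap, file.path(out, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  coef_tab <- coefficient_table(fits)
  write_coefficient_table(coef_tab, file.path(out, "coefficients.csv"))

  # -- manifest -------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config_fingerprint(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- file.path(out, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(config_md5 = unname(tools::md5sum(tmp)),
                   master_seed = config$seed,
                   stage_seeds = list(
                     impute = derive_seed(config$seed, "impute"),
                     tuning = lapply(setNames(config$responses,
                                              config$responses),
                                     function(r) derive_seed(config$seed,
                                                             paste0("tuning:", r)))),
                   package_version = as.character(utils::packageVersion("metabolasso")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- list(cohort = cohort, preprocessed = pp, comparison = comparison,
              problems = problems, searches = searches, fits = fits,
              rocs = rocs, ora = ora, supports = supports,
              overlap = overlap, coefficients = coef_tab,
              out_dir = out)
  class(res) <- "pipeline_result"
  invisible(res)
}

validate_pipeline_inputs <- function(cohort, config) {
  clin <- cohort$clinical
  for (resp in config$responses)
    if (!resp %in% names(clin))
      abort_fmt("response column '%s' missing from the clinical table", resp)
  binary <- intersect(config$responses, c("death30", "survival30"))
  for (b in binary)
    if (!all(clin[[b]] %in% c(0, 1)))
      abort_fmt("outcome column '%s' must be 0/1", b)
  if (is.character(config$clinical_covariates) &&
      !identical(config$clinical_covariates, "significant") &&
      !identical(config$clinical_covariates, "none")) {
    unknown <- setdiff(config$clinical_covariates, names(clin))
    if (length(unknown))
      abort_fmt("unknown clinical covariate(s): %s",
                paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# Clinical variables joining the predictor roster: the comparison-table rows
# with p < 0.05 (numeric columns only), or an explicit config-supplied list.
select_clinical_covariates <- function(config, comparison, clinical) {
  cc <- config$clinical_covariates
  if (identical(cc, "none")) return(character(0))
  if (identical(cc, "significant")) {
    sig <- comparison$feature[comparison$p_value < 0.05]
    return(sig[vapply(sig, function(f) is.numeric(clinical[[f]]),
                      logical(1))])
  }
  cc
}

# ROC comparison of the mortality predictors: septic-shock flag, SOFA,
# PECAM+sTM linear model, the penalised metabolite model, and the two
# metabolites with the largest absolute coefficients.
evaluate_mortality_models <- function(pp, fits, problems, config) {
  clin <- pp$clinical
  y <- clin$death30
  dat <- cbind(clin, as.data.frame(pp$matrix))
  seed <- derive_seed(config$seed, "roc")

  models <- list(
    septic_shock = linear_score(dat, "death30", "septic_shock"),
    sofa = linear_score(dat, "death30", "sofa"),
    pecam_stm = linear_score(dat, "death30", c("pecam", "stm")))
  if ("death30" %in% names(fits)) {
    fit <- fits$death30; prob <- problems$death30
    models$metabolite_model <- as.numeric(prob$X %*% fit$w) + fit$intercept
    w_met <- fit$w[intersect(names(fit$w), colnames(pp$matrix))]
    top2 <- select_features(w_met, rule = "top_k",
                            k = min(2L, sum(w_met != 0)))
    for (m in top2)
      models[[paste0("single_", m)]] <- linear_score(dat, "death30", m)
  }
  lapply(models, function(sc) {
    roc <- roc_auc(sc, y)
    ci <- auc_ci(sc, y, method = "delong")
    list(roc = roc, ci = ci)
  })
}

# Stable, serialisable view of the config for hashing.
config_fingerprint <- function(config) {
  fp <- unclass(config)
  fp$preprocess <- unclass(fp$preprocess)
  if (!is.null(fp$cohort)) fp$cohort <- unclass(fp$cohort)
  fp$out_dir <- NULL
  fp
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  for (m in names(x$fits))
    cat(sprintf("  %s: lambda = %.4g, support = %d\n", m,
                x$fits[[m]]$lambda, sum(x$fits[[m]]$w != 0)))
  for (m in names(x$rocs))
    cat(sprintf("  AUC[%s] = %.3f (%.3f-%.3f)\n", m, x$rocs[[m]]$roc$auc,
                x$rocs[[m]]$ci$low, x$rocs[[m]]$ci$high))
  invisible(x)
}
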