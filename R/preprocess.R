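# Metabolomics preprocessing chain, applied in a fixed order:
#   feature missingness filter -> patient missingness filter ->
#   nonpositive-value filter -> imputation -> log -> Pareto scaling.
#
# The 10% missingness filters use a strict ">" rule (a feature missing in
# exactly 10% of patients is retained). Features containing any observed
# value <= 0 are dropped whole, since nonpositive concentrations indicate
# failed quantification and the log transform is undefined there.

#' Preprocessing configuration
#'
#' @param feature_missing_threshold drop features missing in strictly more
#'   than this fraction of patients (default 0.10).
#' @param patient_missing_threshold drop patients missing strictly more than
#'   this fraction of (retained) features (default 0.10).
#' @param imputation_method `"chained_forest"` (iterative random-forest
#'   imputation with predictive-mean matching, the default), `"knn"`, or
#'   `"median"`.
#' @param imputation_seed seed for the stochastic imputers.
#' @param max_imputation_iterations cap on chained-forest sweeps.
#' @param knn_k neighbours for the knn imputer.
#' @param num_trees random-forest size per imputed feature.
#' @param pmm_k donor pool size for predictive-mean matching.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(feature_missing_threshold = 0.10,
                              patient_missing_threshold = 0.10,
                              imputation_method = c("chained_forest", "knn",
                                                    "median"),
                              imputation_seed = 1L,
                              max_imputation_iterations = 10L,
                              knn_k = 5L,
                              num_trees = 100L,
                              pmm_k = 3L) {
  imputation_method <- match.arg(imputation_method)
  stopifnot(feature_missing_threshold > 0, feature_missing_threshold < 1,
            patient_missing_threshold > 0, patient_missing_threshold < 1,
            knn_k >= 1)
  structure(list(feature_missing_threshold = feature_missing_threshold,
                 patient_missing_threshold = patient_missing_threshold,
                 imputation_method = imputation_method,
                 imputation_seed = as.integer(imputation_seed),
                 max_imputation_iterations = as.integer(max_imputation_iterations),
                 knn_k = as.integer(knn_k),
                 num_trees = as.integer(num_trees),
                 pmm_k = as.integer(pmm_k)),
            class = "preprocess_config")
}

#' Drop features with too many missing values
#'
#' A feature is removed iff `missing_count / n_patients` is strictly greater
#' than `threshold`. Retained feature order is preserved.
#'
#' @param matrix numeric patients x features matrix, `NA` = missing.
#' @param threshold fraction in (0, 1).
#' @return list with `matrix` (retained columns), `removed` (names), and
#'   `missing_fraction` (per input feature).
#' @export
filter_features_by_missingness <- function(matrix, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- colMeans(is.na(matrix))
  drop <- frac > threshold
  if (all(drop)) abort_fmt("all features exceed the missingness threshold")
  list(matrix = matrix[, !drop, drop = FALSE],
       removed = colnames(matrix)[drop],
       missing_fraction = frac)
}

#' Drop patients with too many missing values
#'
#' Mirror of [filter_features_by_missingness()] applied to rows, after the
#' feature filter: a patient is removed iff the fraction of retained features
#' they lack is strictly greater than `threshold`.
#'
#' @inheritParams filter_features_by_missingness
#' @return list with `matrix`, `removed` (row names), `missing_fraction`.
#' @export
filter_patients_by_missingness <- function(matrix, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- rowMeans(is.na(matrix))
  drop <- frac > threshold
  if (all(drop)) abort_fmt("all patients exceed the missingness threshold")
  list(matrix = matrix[!drop, , drop = FALSE],
       removed = rownames(matrix)[drop],
       missing_fraction = frac)
}

#' Drop features containing nonpositive observed values
#'
#' Any feature with an observed value `<= 0` is removed whole (reason
#' `"nonpositive"`): zeros and negatives signal failed quantification and the
#' subsequent log transform is undefined for them.
#'
#' @param matrix numeric patients x features matrix.
#' @return list with `matrix` and `removed`.
#' @export
remove_nonpositive_features <- function(matrix) {
  bad <- apply(matrix, 2, function(x) any(x[!is.na(x)] <= 0))
  list(matrix = matrix[, !bad, drop = FALSE],
       removed = colnames(matrix)[bad])
}

#' Impute missing values
#'
#' Observed cells are returned bit-identical; only `NA` cells are filled.
#' `chained_forest` regresses each incomplete feature on all others with a
#' random forest, filling missing entries by predictive-mean matching against
#' observed donors, and iterates until the mean out-of-bag error stops
#' improving or `max_imputation_iterations` is reached. `knn` averages the
#' `knn_k` nearest patients (Euclidean distance on jointly observed,
#' standardised features); `median` fills per-feature medians. All methods
#' are deterministic under `imputation_seed`.
#'
#' @param matrix numeric patients x features matrix with `NA`s.
#' @param config a [preprocess_config()].
#' @return the completed matrix.
#' @export
impute_missing <- function(matrix, config = preprocess_config()) {
  if (!anyNA(matrix)) return(matrix)
  nobs <- colSums(!is.na(matrix))
  if (any(nobs == 0))
    abort_fmt("feature(s) with no observed values: %s",
              paste(colnames(matrix)[nobs == 0], collapse = ", "))
  out <- switch(config$imputation_method,
                median = impute_median(matrix),
                knn = impute_knn(matrix, config$knn_k),
                chained_forest = with_seed(config$imputation_seed,
                                           impute_chained_forest(matrix, config)))
  # contract: observed cells untouched
  obs <- !is.na(matrix)
  out[obs] <- matrix[obs]
  out
}

impute_median <- function(m) {
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- median(m[!na, j])
  }
  m
}

impute_knn <- function(m, k) {
  ms <- scale(m)
  out <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    for (j in which(is.na(m[i, ]))) {
      donors <- which(!is.na(m[, j]))
      # distance over features observed in both patients
      d <- vapply(donors, function(r) {
        shared <- !is.na(ms[i, ]) & !is.na(ms[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((ms[i, shared] - ms[r, shared])^2))
      }, numeric(1))
      nn <- donors[order(d)][seq_len(min(k, length(donors)))]
      out[i, j] <- mean(m[nn, j])
    }
  }
  out
}

impute_chained_forest <- function(m, config) {
  na_mask <- is.na(m)
  # initialise with medians; visit incomplete features by increasing missingness
  cur <- impute_median(m)
  targets <- order(colSums(na_mask))
  targets <- targets[colSums(na_mask)[targets] > 0]
  prev_oob <- Inf
  for (iter in seq_len(config$max_imputation_iterations)) {
    oob <- numeric(0)
    for (j in targets) {
      miss <- na_mask[, j]
      df <- data.frame(cur[, -j, drop = FALSE])
      df$.y <- cur[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y",
        data = df[!miss, , drop = FALSE],
        num.trees = config$num_trees,
        seed = sample.int(.Machine$integer.max, 1),
        num.threads = 1
      )
      oob <- c(oob, fit$prediction.error)
      pred_miss <- predict(fit, df[miss, , drop = FALSE],
                           num.threads = 1)$predictions
      # predictive-mean matching against observed donors
      pred_obs <- fit$predictions   # out-of-bag predictions for observed rows
      pred_obs[is.na(pred_obs)] <- predict(fit, df[!miss, , drop = FALSE],
                                           num.threads = 1)$predictions[is.na(pred_obs)]
      obs_vals <- m[!miss, j]
      cur[miss, j] <- vapply(pred_miss, function(pv) {
        nn <- order(abs(pred_obs - pv))[seq_len(min(config$pmm_k,
                                                    length(obs_vals)))]
        obs_vals[nn[sample.int(length(nn), 1)]]
      }, numeric(1))
    }
    mean_oob <- mean(oob)
    if (mean_oob >= prev_oob) break
    prev_oob <- mean_oob
  }
  cur
}

#' Log-transform and Pareto-scale a positive matrix
#'
#' Per feature j with log values z: `scaled = (z - mean(z)) / sqrt(sd(z))`,
#' with the natural log and the n-1 sample SD. Pareto scaling damps — but
#' does not remove — differences in feature variance: each scaled feature has
#' mean 0 and variance equal to the SD of its log values.
#'
#' @param matrix numeric patients x features matrix, all values > 0.
#' @return list with `matrix` (scaled), and `params` (data frame with per
#'   feature `mean` and `sd` of the log data, plus the log base used).
#' @export
log_pareto_scale <- function(matrix) {
  if (any(matrix <= 0, na.rm = TRUE) || anyNA(matrix))
    abort_fmt("log_pareto_scale requires a complete, strictly positive matrix")
  z <- log(matrix)
  mu <- colMeans(z)
  s <- apply(z, 2, sd)
  if (any(s == 0))
    abort_fmt("constant feature(s) cannot be Pareto scaled: %s",
              paste(colnames(matrix)[s == 0], collapse = ", "))
  scaled <- sweep(sweep(z, 2, mu), 2, sqrt(s), `/`)
  list(matrix = scaled,
       params = data.frame(feature = colnames(matrix), mean = mu, sd = s,
                           log_base = "natural", row.names = NULL))
}

#' Invert [log_pareto_scale()]
#'
#' @param scaled scaled matrix.
#' @param params the `params` component returned by [log_pareto_scale()].
#' @return the original positive matrix (within numerical tolerance).
#' @export
unscale_log_pareto <- function(scaled, params) {
  z <- sweep(sweep(scaled, 2, sqrt(params$sd), `*`), 2, params$mean, `+`)
  exp(z)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: feature missingness filter, patient missingness filter,
#' nonpositive-value filter, imputation, log transform, Pareto scaling.
#' Clinical covariates pass through untouched (only metabolites are
#' transformed).
#'
#' @param cohort a `cohort`.
#' @param config a [preprocess_config()].
#' @return list of class `preprocessed_cohort`: `matrix` (scaled metabolites),
#'   `imputed` (imputed, unscaled concentrations), `clinical` (filtered to
#'   retained patients), `report` (a `preprocess_report`).
#' @export
preprocess <- function(cohort, config = preprocess_config()) {
  m0 <- cohort$metabolites
  f1 <- filter_features_by_missingness(m0, config$feature_missing_threshold)
  f2 <- filter_patients_by_missingness(f1$matrix,
                                       config$patient_missing_threshold)
  f3 <- remove_nonpositive_features(f2$matrix)
  n_missing <- sum(is.na(f3$matrix))
  imp <- impute_missing(f3$matrix, config)
  sc <- log_pareto_scale(imp)

  removed_features <- rbind(
    data.frame(feature = f1$removed,
               reason = rep("missingness", length(f1$removed))),
    data.frame(feature = f3$removed,
               reason = rep("nonpositive", length(f3$removed))))
  report <- structure(list(
    removed_features = removed_features,
    removed_patients = f2$removed,
    feature_missing_fraction = f1$missing_fraction,
    patient_missing_fraction = f2$missing_fraction,
    imputed_cells = n_missing,
    imputation_method = config$imputation_method,
    scaling = sc$params,
    n_patients = nrow(imp),
    n_features = ncol(imp)), class = "preprocess_report")

  keep <- rownames(imp)
  clin <- cohort$clinical[cohort$clinical$patient_id %in% keep, , drop = FALSE]
  structure(list(matrix = sc$matrix, imputed = imp, clinical = clin,
                 report = report),
            class = "preprocessed_cohort")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("Preprocessing: %d patients x %d features retained\n",
              x$n_patients, x$n_features))
  cat(sprintf("  removed features: %d (missingness %d, nonpositive %d)\n",
              nrow(x$removed_features),
              sum(x$removed_features$reason == "missingness"),
              sum(x$removed_features$reason == "nonpositive")))
  cat(sprintf("  removed patients: %d; imputed cells: %d (%s)\n",
              length(x$removed_patients), x$imputed_cells,
              x$imputation_method))
  invisible(x)
}

#' Serialise a preprocessing report to JSON
#' @param report a `preprocess_report`.
#' @param path output path.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
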