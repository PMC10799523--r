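# Penalty-strength selection: per-bootstrap five-fold cross-validation over a
# log-spaced lambda grid minimising CV mean squared error, the median optimal
# lambda over B bootstrap resamples, and a final fit at that median on the
# full data. Robust for small cohorts, where a single CV split is noisy.

#' Log-spaced penalty grid
#'
#' `n_points` values from `lambda_max` down to `ratio * lambda_max`, strictly
#' decreasing with constant ratio between consecutive values.
#'
#' @param lambda_max largest grid value (typically [lambda_max()]).
#' @param n_points grid size (default 100).
#' @param ratio smallest/largest grid value (default 0.001).
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(lambda_max, n_points = 100L, ratio = 0.001) {
  if (lambda_max < 0) abort_fmt("lambda_max must be nonnegative")
  if (lambda_max == 0) {
    warning("lambda_max is 0; returning the single-point grid {0}")
    return(0)
  }
  if (n_points == 1L) return(lambda_max)
  exp(seq(log(lambda_max), log(ratio * lambda_max), length.out = n_points))
}

# Seeded partition of n observations into k near-equal folds.
cv_folds <- function(n, k, seed) {
  with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
}

#' Cross-validated mean squared error over a penalty grid
#'
#' Seeded random partition into `k` near-equal folds. For each penalty value
#' the model is fitted on k-1 folds and scored on the held-out fold, with
#' standardisation parameters computed on the training folds only and applied
#' to the held-out fold. Returns the per-penalty CV-MSE (mean over held-out
#' squared errors) and the per-fold curves.
#'
#' @param problem a [penalized_problem()] (its raw data are re-standardised
#'   per training split).
#' @param grid decreasing penalty values.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param tol,max_sweeps solver settings for the fold fits. The defaults are
#'   looser than [lasso_fit()]'s because held-out squared error is flat far
#'   below 1e-4 coefficient precision, while near-zero penalties on
#'   ill-conditioned resamples converge slowly at tight tolerances.
#' @return list of class `cv_curve`: `grid`, `mse`, `per_fold` (k x
#'   length(grid)), `folds`.
#' @export
cv_mse <- function(problem, grid, k = 5L, seed = 1L, tol = 1e-4,
                   max_sweeps = 1000L) {
  n <- problem$N
  if (k < 2L) abort_fmt("k must be >= 2")
  if (n < k) abort_fmt("need at least k observations")
  folds <- cv_folds(n, k, seed)
  if (min(table(folds)) < 2L)
    abort_fmt("a fold has fewer than 2 observations")
  per_fold <- matrix(NA_real_, k, length(grid))
  se_sum <- matrix(0, 1, length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    prob_tr <- penalized_problem(problem$X_raw[tr, , drop = FALSE],
                                 problem$y_raw[tr], penalty = problem$v)
    W <- lasso_path(prob_tr, grid, tol = tol, max_sweeps = max_sweeps)
    Xte <- sweep(sweep(problem$X_raw[!tr, , drop = FALSE], 2,
                       prob_tr$x_center), 2, prob_tr$x_scale, `/`)
    pred <- Xte %*% W + prob_tr$y_center   # add training intercept
    err <- (problem$y_raw[!tr] - pred)^2
    per_fold[f, ] <- colMeans(err)
    se_sum <- se_sum + colSums(err)
  }
  structure(list(grid = grid, mse = as.numeric(se_sum) / n,
                 per_fold = per_fold, folds = folds),
            class = "cv_curve")
}

#' Penalty value minimising a CV curve
#'
#' Ties are broken toward the largest (sparsest) penalty.
#' @param curve a `cv_curve`.
#' @return the selected penalty value.
#' @export
select_lambda_cv <- function(curve) {
  curve$grid[which.min(curve$mse)]   # grid is decreasing: first min = largest
}

#' Bootstrap median-penalty selection
#'
#' For each of `B` bootstrap resamples (patients drawn with replacement),
#' runs `k`-fold cross-validation over the penalty grid on the resample and
#' records the CV-MSE-minimising penalty; the selected penalty is the median
#' of the `B` values (for even `B`, the mean of the two central order
#' statistics). The grid is computed once from the full data so per-bootstrap
#' optima are comparable. Resamples whose response has zero variance are
#' redrawn (bounded retries) and logged.
#'
#' @param problem a [penalized_problem()].
#' @param B number of bootstrap resamples (default 500).
#' @param k CV folds per resample (default 5).
#' @param grid_size,grid_ratio passed to [lambda_grid()].
#' @param seed master seed for resampling and fold assignment.
#' @param max_redraws retries per degenerate resample.
#' @param cv_tol,cv_max_sweeps solver settings for the CV fold fits (see
#'   [cv_mse()]).
#' @return object of class `lambda_search`: `per_bootstrap_lambda` (length
#'   B), `median_lambda`, `grid`, `first_curve` (diagnostics for the first
#'   resample), `n_redraws`, `seed`.
#' @export
bootstrap_median_lambda <- function(problem, B = 500L, k = 5L,
                                    grid_size = 100L, grid_ratio = 0.001,
                                    seed = 1L, max_redraws = 100L,
                                    cv_tol = 1e-4, cv_max_sweeps = 1000L) {
  if (B < 1L) abort_fmt("B must be >= 1")
  grid <- lambda_grid(lambda_max(problem), grid_size, grid_ratio)
  n <- problem$N
  lam <- numeric(B)
  n_redraws <- 0L
  first_curve <- NULL
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- NULL
      for (try in seq_len(max_redraws)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (var(problem$y_raw[cand]) > 0) { idx <- cand; break }
        n_redraws <- n_redraws + 1L
      }
      if (is.null(idx))
        abort_fmt("bootstrap resample response variance stayed 0 after %d redraws",
                  max_redraws)
      prob_b <- penalized_problem(problem$X_raw[idx, , drop = FALSE],
                                  problem$y_raw[idx], penalty = problem$v)
      fold_seed <- sample.int(2147483646L, 1)
      curve <- cv_mse(prob_b, grid, k = k, seed = fold_seed,
                      tol = cv_tol, max_sweeps = cv_max_sweeps)
      if (b == 1L) first_curve <- curve
      lam[b] <- select_lambda_cv(curve)
    }
  })
  structure(list(per_bootstrap_lambda = lam,
                 median_lambda = median(lam),
                 grid = grid, first_curve = first_curve,
                 n_redraws = n_redraws, seed = seed, B = B, k = k),
            class = "lambda_search")
}

#' Final fit at the selected penalty
#'
#' Refits the penalised model on all observations at the (median) selected
#' penalty; the nonzero coefficients of this fit are the selected biomarkers.
#'
#' @param problem a [penalized_problem()].
#' @param median_lambda the selected penalty, `>= 0`.
#' @inheritParams lasso_fit
#' @return a `lasso_fit`.
#' @export
final_fit <- function(problem, median_lambda, tol = 1e-7, max_sweeps = 1e4) {
  fit <- lasso_fit(problem, median_lambda, tol = tol, max_sweeps = max_sweeps)
  if (all(fit$w == 0))
    warning("final fit has empty support (lambda at or above lambda_max)")
  fit
}

#' @export
print.lambda_search <- function(x, ...) {
  cat(sprintf("Bootstrap penalty search: B = %d, k = %d\n", x$B, x$k))
  cat(sprintf("  median lambda = %.6g (grid %.3g..%.3g, %d points)\n",
              x$median_lambda, max(x$grid), min(x$grid), length(x$grid)))
  if (x$n_redraws > 0)
    cat(sprintf("  degenerate resamples redrawn: %d\n", x$n_redraws))
  invisible(x)
}

#' Serialise a penalty search to JSON
#' @param search a `lambda_search`.
#' @param path output path.
#' @export
write_lambda_search <- function(search, path) {
  jsonlite::write_json(list(per_bootstrap_lambda = search$per_bootstrap_lambda,
                            median_lambda = search$median_lambda,
                            grid = search$grid, seed = search$seed,
                            B = search$B, k = search$k,
                            n_redraws = search$n_redraws),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
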