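# Penalised least-squares core. The objective is
#
#   Cost(w) = (1/2N) * sum_i ( y_i - sum_j w_j x_ij )^2
#             + lambda * sum_j v_j |w_j|
#
# where v is a per-predictor penalty vector (all 1 by default). The intercept
# is handled implicitly: X columns are centred and scaled to unit sample
# variance and y is centred, so the unpenalised intercept equals mean(y).
# Coefficients are reported on the standardised scale, with a back-transform
# to the raw scale available.

#' Construct a standardised penalised regression problem
#'
#' Centres each column of `X` and scales non-constant columns to unit sample
#' variance (n-1 denominator); centres `y`. Constant columns are retained
#' (centred to zero) and can never enter the model. Raw data and scaling
#' parameters are kept for cross-validation and back-transformation.
#'
#' @param X numeric N x p design matrix.
#' @param y numeric response of length N.
#' @param penalty nonnegative per-predictor penalty vector `v` (default all
#'   1). Predictors with `v_j = 0` are unpenalised.
#' @param standardize centre/scale the design (default TRUE; set FALSE only
#'   if `X` is already standardised and `y` centred).
#' @return an object of class `penalized_problem`.
#' @export
penalized_problem <- function(X, y, penalty = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    abort_fmt("X has %d rows but y has length %d", nrow(X), length(y))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    abort_fmt("X and y must be finite (impute before fitting)")
  p <- ncol(X)
  v <- if (is.null(penalty)) rep(1, p) else as.numeric(penalty)
  if (length(v) != p || any(v < 0))
    abort_fmt("penalty vector must be nonnegative with length ncol(X)")
  nms <- colnames(X)
  if (is.null(nms)) nms <- sprintf("x%d", seq_len(p))

  if (standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd)
    x_scale[x_scale == 0] <- 1      # constant column: centre only
    Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
    y_center <- mean(y)
    ys <- y - y_center
  } else {
    x_center <- rep(0, p); x_scale <- rep(1, p)
    Xs <- X; y_center <- 0; ys <- y
  }
  structure(list(X = Xs, y = ys, X_raw = X, y_raw = y,
                 N = nrow(X), p = p, v = v, feature_names = nms,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center),
            class = "penalized_problem")
}

#' Evaluate the penalised cost function
#'
#' `(1/2N) * sum((y - X w)^2) + lambda * sum(v * |w|)` on the standardised
#' problem.
#'
#' @param problem a [penalized_problem()].
#' @param w coefficient vector of length p.
#' @param lambda penalty strength, `>= 0`.
#' @return the cost value.
#' @export
lasso_cost <- function(problem, w, lambda) {
  if (lambda < 0) abort_fmt("lambda must be nonnegative")
  if (length(w) != problem$p)
    abort_fmt("w must have length %d", problem$p)
  r <- problem$y - problem$X %*% w
  sum(r^2) / (2 * problem$N) + lambda * sum(problem$v * abs(w))
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`: the solution of the one-dimensional
#' L1-penalised least-squares subproblem.
#'
#' @param z numeric vector.
#' @param gamma threshold, `>= 0`.
#' @return thresholded values.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) abort_fmt("gamma must be nonnegative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Smallest penalty with an all-zero solution
#'
#' `max_j |x_j' y| / (N v_j)` over predictors with `v_j > 0`; at any
#' `lambda >= lambda_max` the solution of the penalised problem is exactly
#' zero. Predictors with `v_j = 0` are unpenalised and excluded.
#'
#' @param problem a [penalized_problem()].
#' @return the critical penalty value.
#' @export
lambda_max <- function(problem) {
  pen <- problem$v > 0
  if (!any(pen)) abort_fmt("lambda_max undefined: all penalty weights are 0")
  g <- abs(crossprod(problem$X[, pen, drop = FALSE], problem$y)) / problem$N
  max(g / problem$v[pen])
}

#' Fit the penalised least-squares model at one penalty value
#'
#' Cyclic coordinate descent with exact one-dimensional updates
#' `w_j <- soft_threshold((1/N) x_j' r_(-j), lambda v_j) / (x_j'x_j / N)`,
#' iterated until the largest coefficient change in a sweep falls below
#' `tol` or `max_sweeps` is reached. A converged fit satisfies the KKT
#' conditions of the objective (see [kkt_residuals()]).
#'
#' @param problem a [penalized_problem()].
#' @param lambda penalty strength, `>= 0`.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps sweep cap.
#' @param w0 optional warm-start coefficients.
#' @return object of class `lasso_fit`: `w` (named, standardised scale),
#'   `intercept` (mean of raw y), `lambda`, `n_sweeps`, `converged`,
#'   `final_cost`.
#' @export
lasso_fit <- function(problem, lambda, tol = 1e-7, max_sweeps = 1e4,
                      w0 = NULL) {
  if (lambda < 0) abort_fmt("lambda must be nonnegative")
  if (is.null(w0)) w0 <- rep(0, problem$p)
  res <- cd_lasso_cpp(problem$X, problem$y, lambda, problem$v,
                      as.numeric(w0), tol, as.integer(max_sweeps))
  w <- as.numeric(res$w)
  names(w) <- problem$feature_names
  structure(list(w = w, intercept = problem$y_center, lambda = lambda,
                 n_sweeps = res$n_sweeps, converged = res$converged,
                 final_cost = res$final_cost),
            class = "lasso_fit")
}

#' Warm-started solution path over a decreasing penalty grid
#'
#' @param problem a [penalized_problem()].
#' @param lambdas strictly decreasing penalty values.
#' @inheritParams lasso_fit
#' @return p x length(lambdas) coefficient matrix (standardised scale).
#' @export
lasso_path <- function(problem, lambdas, tol = 1e-7, max_sweeps = 1e4) {
  W <- cd_lasso_path_cpp(problem$X, problem$y, as.numeric(lambdas),
                         problem$v, tol, as.integer(max_sweeps))
  dimnames(W) <- list(problem$feature_names, NULL)
  W
}

#' KKT residuals of a candidate solution
#'
#' For each predictor returns how far the stationarity condition is violated:
#' where `w_j = 0` the violation is `max(|(1/N) x_j'r| - lambda v_j, 0)`;
#' where `w_j != 0` it is `|(1/N) x_j'r - lambda v_j sign(w_j)|`. A solution
#' is optimal iff all residuals are zero (numerically, below ~1e-6).
#'
#' @param problem a [penalized_problem()].
#' @param w coefficients.
#' @param lambda penalty used.
#' @return numeric vector of per-predictor violations.
#' @export
kkt_residuals <- function(problem, w, lambda) {
  r <- problem$y - problem$X %*% w
  g <- as.numeric(crossprod(problem$X, r)) / problem$N
  out <- numeric(problem$p)
  zero <- w == 0
  out[zero] <- pmax(abs(g[zero]) - lambda * problem$v[zero], 0)
  out[!zero] <- abs(g[!zero] - lambda * problem$v[!zero] * sign(w[!zero]))
  out
}

#' Back-transform standardised coefficients to the raw data scale
#'
#' @param fit a `lasso_fit`.
#' @param problem the [penalized_problem()] it was fitted on.
#' @return list with `coefficients` (raw scale) and `intercept`.
#' @export
coef_raw_scale <- function(fit, problem) {
  b <- fit$w / problem$x_scale
  list(coefficients = setNames(b, problem$feature_names),
       intercept = problem$y_center - sum(b * problem$x_center))
}

#' Predict from a fit on new raw-scale data
#' @param object a `lasso_fit`.
#' @param problem the training [penalized_problem()].
#' @param newdata raw-scale matrix with the training columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict_lasso <- function(object, problem, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, problem$x_center), 2,
              problem$x_scale, `/`)
  as.numeric(object$intercept + Xs %*% object$w)
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$w != 0)
  cat(sprintf("Penalised fit: lambda = %.6g, support %d/%d, %s after %d sweeps\n",
              x$lambda, nz, length(x$w),
              if (x$converged) "converged" else "NOT converged", x$n_sweeps))
  invisible(x)
}

#' L1-penalised logistic regression (optional variant)
#'
#' Minimises `(1/N) * sum_i log(1 + exp(-t_i * eta_i)) + lambda sum_j v_j|w_j|`
#' (t = +/-1 coded response) by iteratively re-weighted coordinate descent on
#' a quadratic majoriser of the logistic loss (curvature bound 1/4). Provided
#' for binary outcomes as an alternative to the squared-error default; not
#' used by the main pipeline.
#'
#' @param problem a [penalized_problem()] whose raw response is 0/1.
#' @param lambda penalty strength.
#' @param tol outer-loop tolerance on coefficient change.
#' @param max_iter outer iterations.
#' @return a `lasso_fit` with an extra `intercept` on the logit scale.
#' @export
lasso_fit_logistic <- function(problem, lambda, tol = 1e-6, max_iter = 100L) {
  y01 <- problem$y_raw
  if (!all(y01 %in% c(0, 1)))
    abort_fmt("logistic variant requires a 0/1 response")
  X <- problem$X
  n <- problem$N
  w <- rep(0, problem$p); b0 <- qlogis(mean(pmin(pmax(y01, 0.05), 0.95)))
  for (it in seq_len(max_iter)) {
    eta <- b0 + as.numeric(X %*% w)
    mu <- plogis(eta)
    # majoriser: working response with fixed curvature 1/4
    z <- eta + 4 * (y01 - mu)
    prob_ls <- structure(list(X = X, y = z - mean(z), X_raw = X, y_raw = z,
                              N = n, p = problem$p, v = problem$v,
                              feature_names = problem$feature_names,
                              x_center = rep(0, problem$p),
                              x_scale = rep(1, problem$p),
                              y_center = mean(z)),
                         class = "penalized_problem")
    fit <- lasso_fit(prob_ls, 4 * lambda, tol = tol / 10)
    delta <- max(abs(fit$w - w), abs(mean(z) - b0))
    w <- fit$w; b0 <- mean(z)
    if (delta < tol) break
  }
  structure(list(w = w, intercept = b0, lambda = lambda, n_sweeps = it,
                 converged = it < max_iter, final_cost = NA_real_,
                 family = "binomial"),
            class = "lasso_fit")
}
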