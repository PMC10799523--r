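# ROC/AUC evaluation of mortality predictors: a single binary flag (septic
# shock), an integer severity score (SOFA), an unpenalised two-marker linear
# model (PECAM + sTM), the penalised metabolite model, and single
# metabolites. AUC is the tie-aware concordance probability, identical to
# the trapezoidal area under the empirical curve and to U/(n_pos*n_neg).

# tie-aware concordance AUC from midranks
auc_rank <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' In-sample linear risk scores
#'
#' Ordinary (unpenalised) least-squares fit of a binary outcome on the named
#' features over all observations; the in-sample fitted values are returned
#' as risk scores. With a rank-deficient design the minimum-norm solution is
#' used, with a warning.
#'
#' @param data data frame holding outcome and features.
#' @param outcome name of the binary outcome column.
#' @param features character vector of predictor columns.
#' @return numeric vector of fitted values.
#' @export
linear_score <- function(data, outcome, features) {
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort_fmt("outcome '%s' must be 0/1", outcome)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, features, drop = FALSE]))
  storage.mode(X) <- "double"
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear design; using the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else {
    beta <- qr.coef(qx, y)
  }
  as.numeric(X %*% beta)
}

#' Empirical ROC curve and AUC
#'
#' AUC is the concordance probability
#' `(#concordant case/control pairs + 0.5 #tied pairs) / (n_pos * n_neg)`,
#' computed from midranks; it equals the trapezoidal area under the
#' empirical curve. Operating points are taken at midpoints between adjacent
#' distinct scores (plus sentinels), so the curve runs from (0, 1) to (1, 0)
#' in (1-specificity, sensitivity) space.
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels 0/1 (or two-level) case labels; 1 = case.
#' @return object of class `roc_curve`: `points` (threshold, sensitivity,
#'   specificity), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  lab <- as.integer(as.factor(labels)) - 1L
  if (length(unique(lab)) != 2L)
    abort_fmt("both classes must be present")
  pos <- lab == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- auc_rank(scores, pos)

  s <- sort(unique(scores))
  thr <- c(Inf, rev(if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)),
           -Inf)
  pts <- t(vapply(thr, function(t) {
    c(sensitivity = mean(scores[pos] >= t),
      specificity = mean(scores[!pos] < t))
  }, numeric(2)))
  structure(list(points = data.frame(threshold = thr,
                                     sensitivity = pts[, 1],
                                     specificity = pts[, 2]),
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' Confidence interval for an AUC
#'
#' `"delong"` (default): the DeLong structural-components variance with a
#' normal-theory 95% interval, clipped to `[0, 1]`; with zero variance
#' (perfect separation) the degenerate interval `[auc, auc]` is returned
#' with a warning. `"bootstrap"`: stratified resampling of cases and controls
#' with percentile 2.5/97.5 limits, seeded.
#'
#' @param scores,labels as in [roc_auc()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param seed bootstrap seed.
#' @param B bootstrap replicates (default 2000).
#' @param conf confidence level (default 0.95).
#' @return list with `low`, `high`, `auc`, `method`, `se` (delong only).
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   seed = 1L, B = 2000L, conf = 0.95) {
  method <- match.arg(method)
  lab <- as.integer(as.factor(labels)) - 1L
  pos <- lab == 1L
  if (sum(pos) < 2L || sum(!pos) < 2L)
    abort_fmt("each class needs at least 2 members")
  auc <- roc_auc(scores, labels)$auc
  if (method == "delong") {
    x <- scores[pos]; yv <- scores[!pos]
    m <- length(x); n <- length(yv)
    # structural components via midranks (DeLong-Sun-Sun placements)
    rall <- rank(c(x, yv))
    v10 <- (rall[seq_len(m)] - rank(x)) / n          # P(Y < x_i) + .5 ties
    v01 <- 1 - (rall[m + seq_len(n)] - rank(yv)) / m # P(y_j < X) + .5 ties
    s <- var(v10) / m + var(v01) / n
    if (s <= 0) {
      warning("zero DeLong variance (perfect separation); degenerate interval")
      return(list(low = auc, high = auc, auc = auc, method = method, se = 0))
    }
    z <- qnorm(1 - (1 - conf) / 2)
    list(low = max(0, auc - z * sqrt(s)), high = min(1, auc + z * sqrt(s)),
         auc = auc, method = method, se = sqrt(s))
  } else {
    ip <- which(pos); ineg <- which(!pos)
    reps <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- c(sample(ip, length(ip), replace = TRUE),
                 sample(ineg, length(ineg), replace = TRUE))
        auc_rank(scores[idx], lab[idx] == 1L)
      }, numeric(1))
    })
    q <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 7)
    list(low = unname(q[1]), high = unname(q[2]), auc = auc,
         method = method, se = NA_real_)
  }
}

#' Cross-validated AUC (honest alternative to in-sample scoring)
#'
#' k-fold refit of the unpenalised linear score with out-of-fold predictions
#' pooled into a single AUC.
#'
#' @inheritParams linear_score
#' @param k folds.
#' @param seed fold seed.
#' @return list with `auc` and the out-of-fold `scores`.
#' @export
cv_auc <- function(data, outcome, features, k = 5L, seed = 1L) {
  n <- nrow(data)
  folds <- cv_folds(n, k, seed)
  sc <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit_dat <- data[tr, , drop = FALSE]
    y <- fit_dat[[outcome]]
    X <- cbind(1, as.matrix(fit_dat[, features, drop = FALSE]))
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    Xte <- cbind(1, as.matrix(data[!tr, features, drop = FALSE]))
    sc[!tr] <- as.numeric(Xte %*% beta)
  }
  list(auc = roc_auc(sc, data[[outcome]])$auc, scores = sc)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d cases / %d controls, %d operating points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @importFrom stats qnorm qlogis
NULL
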