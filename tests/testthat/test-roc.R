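# ROC module: linear risk scores, tie-aware AUC, the U-statistic identity,
# and confidence intervals.

test_that("linear_score reproduces closed-form least squares", {
  df <- data.frame(y = c(0, 0, 1, 1, 1, 0),
                   x1 = c(1, 2, 3, 4, 5, 6),
                   x2 = c(2, 1, 4, 3, 6, 5))
  sc <- linear_score(df, "y", c("x1", "x2"))
  X <- cbind(1, df$x1, df$x2)
  beta <- solve(crossprod(X), crossprod(X, df$y))
  expect_equal(sc, as.numeric(X %*% beta), tolerance = 1e-10)
  # single binary feature: exactly the two group means
  df2 <- data.frame(y = c(0, 1, 1, 0, 1), f = c(0, 0, 1, 1, 1))
  sc2 <- linear_score(df2, "y", "f")
  expect_identical(length(unique(round(sc2, 12))), 2L)
  expect_equal(sort(unique(sc2)), c(mean(df2$y[df2$f == 0]),
                                    mean(df2$y[df2$f == 1])))
  # affine transform of a feature leaves fitted values unchanged
  df$x1b <- 3 * df$x1 - 7
  expect_equal(linear_score(df, "y", c("x1b", "x2")), sc, tolerance = 1e-10)
  # collinear design: minimum-norm with warning
  df$x3 <- df$x1 + df$x2
  expect_warning(sc3 <- linear_score(df, "y", c("x1", "x2", "x3")),
                 "collinear")
  expect_equal(sc3, sc, tolerance = 1e-8)
})

test_that("AUC handles separation, ties, and the pair-counting example", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("curve runs from (0,1) to (1,0) and traps the same area as the AUC", {
  set.seed(1)
  sc <- round(rnorm(40), 1)             # ties likely
  lab <- rbinom(40, 1, 0.4)
  r <- roc_auc(sc, lab)
  pts <- r$points
  expect_equal(c(pts$sensitivity[1], pts$specificity[1]), c(0, 1))
  expect_equal(c(pts$sensitivity[nrow(pts)], pts$specificity[nrow(pts)]),
               c(1, 0))
  fpr <- 1 - pts$specificity; tpr <- pts$sensitivity
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC equals U/(n_pos*n_neg) and survives monotone transforms", {
  set.seed(2)
  for (i in 1:20) {
    sc <- sample(seq(0, 5, by = 0.5), 30, replace = TRUE)
    lab <- c(rep(1, 12), rep(0, 18))[sample(30)]
    r <- roc_auc(sc, lab)
    mw <- mann_whitney(sc[lab == 1], sc[lab == 0])
    expect_equal(r$auc * r$n_pos * r$n_neg, mw$U, tolerance = 1e-12)
    expect_equal(roc_auc(exp(sc), lab)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on tied data", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- round(rnorm(60), 1)
  lab <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(sc, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("DeLong CI matches pROC and brackets the AUC; inversion reflects it", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- c(rnorm(30, 1), rnorm(40))
  lab <- c(rep(1, 30), rep(0, 40))
  ci <- auc_ci(sc, lab, method = "delong")
  pr <- pROC::ci.auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<"),
                     method = "delong")
  expect_equal(c(ci$low, ci$high), as.numeric(pr[c(1, 3)]), tolerance = 1e-9)
  expect_true(ci$low <= ci$auc && ci$auc <= ci$high)
  inv <- auc_ci(-sc, lab, method = "delong")
  expect_equal(inv$auc, 1 - ci$auc, tolerance = 1e-12)
  expect_equal(c(inv$low, inv$high), c(1 - ci$high, 1 - ci$low),
               tolerance = 1e-9)
})

test_that("DeLong and bootstrap intervals agree on moderately separated data", {
  set.seed(5)
  sc <- c(rnorm(50, 0.8), rnorm(50))
  lab <- c(rep(1, 50), rep(0, 50))
  dl <- auc_ci(sc, lab, method = "delong")
  bs <- auc_ci(sc, lab, method = "bootstrap", B = 1e4, seed = 6)
  expect_lt(abs(dl$low - bs$low), 0.02)
  expect_lt(abs(dl$high - bs$high), 0.02)
  expect_identical(auc_ci(sc, lab, method = "bootstrap", B = 500, seed = 7),
                   auc_ci(sc, lab, method = "bootstrap", B = 500, seed = 7))
})

test_that("perfect separation yields a degenerate DeLong interval", {
  expect_warning(ci <- auc_ci(c(1, 2, 9, 10), c(0, 0, 1, 1)), "separation")
  expect_equal(c(ci$low, ci$high), c(1, 1))
})

test_that("cross-validated AUC is below the in-sample AUC on overfit designs", {
  set.seed(8)
  n <- 50
  dat <- as.data.frame(matrix(rnorm(n * 20), n, 20))
  dat$y <- rbinom(n, 1, 0.4)                 # pure noise predictors
  feats <- names(dat)[1:20]
  insample <- roc_auc(linear_score(dat, "y", feats), dat$y)$auc
  cv <- cv_auc(dat, "y", feats, k = 5, seed = 9)
  expect_gt(insample, cv$auc)
})
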