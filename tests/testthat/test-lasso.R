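# Penalised least-squares core: cost function, soft threshold, lambda_max,
# coordinate descent against closed-form, convex-solver and glmnet oracles.

test_that("cost function evaluates the penalised objective exactly", {
  prob <- penalized_problem(matrix(c(1, -1), 2, 1), c(1, -1),
                            standardize = FALSE)
  expect_equal(lasso_cost(prob, 0, 5), 0.5)                 # w = 0
  expect_equal(lasso_cost(prob, 1, 0), 0)                   # exact fit, no penalty
  expect_equal(lasso_cost(prob, 0.5, 0.1), 0.175)           # hand evaluation
  expect_error(lasso_cost(prob, 0.5, -1), "nonnegative")
})

test_that("soft threshold matches its definition", {
  expect_identical(soft_threshold(1.7, 0), 1.7)
  expect_identical(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(0.8, 0.5), 0.3)
  expect_equal(soft_threshold(-0.8, 0.5), -0.3)
})

test_that("lambda_max is the smallest penalty with empty support", {
  prob <- penalized_problem(matrix(c(1, -1), 2, 1), c(2, -2),
                            standardize = FALSE)
  expect_equal(lambda_max(prob), 2)
  zero <- penalized_problem(matrix(c(1, -1), 2, 1), c(0, 0),
                            standardize = FALSE)
  expect_equal(lambda_max(zero), 0)

  rp <- random_problem(30, 6, sparsity = 2, seed = 2)
  lm_ <- lambda_max(rp)
  expect_true(all(lasso_fit(rp, 1.0001 * lm_)$w == 0))
  expect_true(any(lasso_fit(rp, 0.95 * lm_)$w != 0))
  allzero <- penalized_problem(matrix(rnorm(20), 10, 2), rnorm(10),
                               penalty = c(0, 0))
  expect_error(lambda_max(allzero), "penalty weights")
})

test_that("orthonormal designs reproduce the closed-form solution", {
  n <- 40
  prob <- orthonormal_problem(n, 2, seed = 3)
  # choose y so the per-feature OLS estimates are exactly (0.8, -0.2)
  y <- as.numeric(prob$X %*% c(0.8, -0.2))
  prob <- penalized_problem(prob$X, y, standardize = FALSE)
  fit <- lasso_fit(prob, 0.5)
  expect_equal(unname(fit$w), c(0.3, 0), tolerance = 1e-10)

  # general orthonormal case with noise, several lambdas
  prob2 <- orthonormal_problem(50, 6, seed = 4)
  ols <- as.numeric(crossprod(prob2$X, prob2$y)) / prob2$N
  for (lam in c(0.02, 0.1, 0.3)) {
    fit2 <- lasso_fit(prob2, lam)
    expect_equal(unname(fit2$w), soft_threshold(ols, lam), tolerance = 1e-6)
  }
})

test_that("converged fits satisfy the KKT conditions", {
  for (s in 1:5) {
    prob <- random_problem(25, 8, sparsity = 3, seed = s)
    lam <- 0.3 * lambda_max(prob)
    fit <- lasso_fit(prob, lam)
    expect_true(fit$converged)
    expect_lt(max(kkt_residuals(prob, fit$w, lam)), 1e-6)
  }
})

test_that("solutions match an independent proximal-gradient solver and glmnet", {
  skip_if_not_installed("glmnet")
  prob <- random_problem(10, 4, sparsity = 2, seed = 6)
  lam <- 0.1
  fit <- lasso_fit(prob, lam)
  expect_lt(max(abs(fit$w - fista_lasso(prob, lam))), 1e-5)
  g <- glmnet::glmnet(prob$X, prob$y, lambda = lam, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$w - as.numeric(g$beta))), 1e-5)
  # no random perturbation of the solution lowers the cost
  set.seed(6)
  base <- lasso_cost(prob, fit$w, lam)
  worse <- replicate(1e4, {
    lasso_cost(prob, fit$w + runif(prob$p, -0.05, 0.05), lam)
  })
  expect_true(all(worse >= base - 1e-12))
})

test_that("a nonuniform penalty vector shifts shrinkage between predictors", {
  prob <- orthonormal_problem(50, 3, seed = 8)
  y <- as.numeric(prob$X %*% c(1, 1, 1))
  prob <- penalized_problem(prob$X, y, penalty = c(1, 2, 0),
                            standardize = FALSE)
  fit <- lasso_fit(prob, 0.4)
  expect_equal(unname(fit$w), c(0.6, 0.2, 1), tolerance = 1e-7)
})

test_that("cost is non-increasing over sweeps and the sweep cap is honoured", {
  prob <- random_problem(30, 10, sparsity = 4, seed = 9)
  lam <- 0.05 * lambda_max(prob)
  costs <- vapply(1:12, function(s)
    lasso_fit(prob, lam, tol = 0, max_sweeps = s)$final_cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
  expect_false(lasso_fit(prob, lam, tol = 1e-14, max_sweeps = 1)$converged)
})

test_that("warm-started paths match cold starts and shrink support with lambda", {
  prob <- random_problem(40, 12, sparsity = 4, seed = 10)
  grid <- lambda_grid(lambda_max(prob), 20, 0.01)
  W <- lasso_path(prob, grid)
  cold <- vapply(grid, function(l) lasso_fit(prob, l)$w, numeric(prob$p))
  expect_lt(max(abs(W - cold)), 1e-6)
  supp <- colSums(W != 0)          # grid decreasing: support weakly grows
  expect_true(all(diff(supp) >= 0))
})

test_that("lambda = 0 reproduces least squares on full-rank designs", {
  prob <- random_problem(50, 5, sparsity = 2, seed = 11)
  ols <- qr.solve(prob$X, prob$y)
  expect_lt(max(abs(lasso_fit(prob, 0)$w - ols)), 1e-6)
})

test_that("coefficients shrink toward zero relative to OLS on orthonormal designs", {
  prob <- orthonormal_problem(60, 8, seed = 12)
  ols <- as.numeric(crossprod(prob$X, prob$y)) / prob$N
  fit <- lasso_fit(prob, 0.05)
  expect_true(all(abs(fit$w) <= abs(ols) + 1e-6))
  expect_true(all(sign(fit$w[fit$w != 0]) == sign(ols[fit$w != 0])))
})

test_that("back-transform returns raw-scale coefficients that predict raw y", {
  set.seed(13)
  X <- matrix(rnorm(40 * 4, mean = 5, sd = 2), 40, 4)
  y <- X %*% c(2, 0, -1, 0) + rnorm(40, sd = 0.1) + 3
  prob <- penalized_problem(X, y)
  fit <- lasso_fit(prob, 0.01)
  raw <- coef_raw_scale(fit, prob)
  pred_raw <- raw$intercept + X %*% raw$coefficients
  expect_equal(as.numeric(pred_raw), predict_lasso(fit, prob, X),
               tolerance = 1e-10)
})

test_that("non-finite input is rejected", {
  expect_error(penalized_problem(matrix(c(1, NA, 2, 3), 2), c(1, 2)),
               "finite")
})

test_that("logistic variant separates a linearly structured outcome", {
  set.seed(14)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - 1.5 * X[, 2]))
  prob <- penalized_problem(X, y)
  fit <- lasso_fit_logistic(prob, 0.02)
  expect_gt(fit$w[1], 0)
  expect_lt(fit$w[2], 0)
  expect_gt(sum(fit$w == 0), 0)    # still sparse
})
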