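# Penalty selection: grid construction, cross-validated MSE, bootstrap
# median, final fit delegation, determinism and recovery behaviour.

test_that("lambda grid is log-spaced with the requested endpoints", {
  expect_equal(lambda_grid(1, 2, 0.01), c(1, 0.01))
  g <- lambda_grid(1, 3, 0.01)
  expect_equal(g, c(1, 0.1, 0.01), tolerance = 1e-12)
  g2 <- lambda_grid(2.5, 30, 0.001)
  expect_equal(diff(log(g2)), rep(diff(log(g2))[1], 29), tolerance = 1e-12)
  expect_warning(g0 <- lambda_grid(0), "single-point")
  expect_identical(g0, 0)
})

test_that("cv_mse is deterministic under its seed and validates folds", {
  prob <- random_problem(30, 6, sparsity = 2, seed = 1)
  grid <- lambda_grid(lambda_max(prob), 15, 0.01)
  c1 <- cv_mse(prob, grid, k = 5, seed = 7)
  c2 <- cv_mse(prob, grid, k = 5, seed = 7)
  expect_identical(c1$folds, c2$folds)
  expect_identical(c1$mse, c2$mse)
  expect_false(identical(cv_mse(prob, grid, k = 5, seed = 8)$folds, c1$folds))
  expect_error(cv_mse(prob, grid, k = 1, seed = 1), "k must be")
})

test_that("noiseless duplicated-signal data select the smallest penalty", {
  set.seed(2)
  X <- matrix(rnorm(10 * 3), 10, 3)[rep(1:10, 4), ]    # duplicated rows
  y <- as.numeric(X %*% c(1, -1, 0.5))                 # exact linear signal
  prob <- penalized_problem(X, y)
  grid <- lambda_grid(lambda_max(prob), 25, 1e-5)
  curve <- cv_mse(prob, grid, k = 5, seed = 3)
  expect_equal(select_lambda_cv(curve), min(grid))
})

test_that("pure-noise responses select penalties in the upper half of the grid", {
  hits <- vapply(1:50, function(s) {
    prob <- random_problem(40, 10, sparsity = 0, seed = 100 + s)
    grid <- lambda_grid(lambda_max(prob), 20, 0.001)
    lam <- select_lambda_cv(cv_mse(prob, grid, k = 5, seed = s))
    lam >= min(grid) * sqrt(max(grid) / min(grid))   # geometric midpoint
  }, logical(1))
  expect_gte(mean(hits), 0.70)
})

test_that("bootstrap median lambda follows the median convention and seed", {
  prob <- random_problem(40, 8, sparsity = 3, noise = 0.5, seed = 4)
  s1 <- bootstrap_median_lambda(prob, B = 4, k = 4, grid_size = 15, seed = 5)
  expect_length(s1$per_bootstrap_lambda, 4)
  srt <- sort(s1$per_bootstrap_lambda)
  expect_equal(s1$median_lambda, mean(srt[2:3]))
  expect_true(s1$median_lambda >= min(s1$grid) &
                s1$median_lambda <= max(s1$grid))
  s2 <- bootstrap_median_lambda(prob, B = 4, k = 4, grid_size = 15, seed = 5)
  expect_identical(s1$per_bootstrap_lambda, s2$per_bootstrap_lambda)
})

test_that("degenerate bootstrap resamples are redrawn", {
  set.seed(6)
  X <- matrix(rnorm(24), 12, 2)
  y <- c(1, rep(0, 11))                 # resamples often all-zero
  prob <- penalized_problem(X, y)
  s <- bootstrap_median_lambda(prob, B = 30, k = 3, grid_size = 10, seed = 6)
  expect_gt(s$n_redraws, 0)
  expect_length(s$per_bootstrap_lambda, 30)
})

test_that("final fit delegates bit-identically to lasso_fit", {
  prob <- random_problem(30, 6, sparsity = 2, seed = 7)
  lam <- 0.2 * lambda_max(prob)
  expect_identical(final_fit(prob, lam)$w, lasso_fit(prob, lam)$w)
  expect_warning(empty <- final_fit(prob, 1.1 * lambda_max(prob)),
                 "empty support")
  expect_true(all(empty$w == 0))
})

test_that("median lambda is stable across master seeds on a fixed problem", {
  prob <- random_problem(60, 15, sparsity = 4, noise = 0.5, seed = 8)
  meds <- vapply(1:10, function(s)
    bootstrap_median_lambda(prob, B = 100, k = 5, grid_size = 40,
                            seed = s)$median_lambda, numeric(1))
  step <- abs(diff(log(lambda_grid(1, 40, 0.001)))[1])
  expect_lt(IQR(log(meds)), step / 2)
})

test_that("planted coefficients are recovered with correct signs (single replicate)", {
  set.seed(9)
  n <- 100; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1, 1, -1, 1, rep(0, p - 4))
  y <- as.numeric(X %*% beta + rnorm(n, sd = 0.5))
  prob <- penalized_problem(X, y)
  s <- bootstrap_median_lambda(prob, B = 50, k = 5, grid_size = 40, seed = 9)
  fit <- final_fit(prob, s$median_lambda)
  expect_true(all(fit$w[1:4] != 0))
  expect_identical(sign(fit$w[1:4]), sign(beta[1:4]), ignore_attr = TRUE)
  expect_true(all(abs(fit$w) <= abs(qr.solve(prob$X, prob$y)) + 0.05))
})
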