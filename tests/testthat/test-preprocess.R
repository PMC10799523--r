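# Preprocessing chain: strict 10% filters, whole-feature nonpositive removal,
# imputation contract, log + Pareto scaling identities.

test_that("feature filter uses a strict > rule at the boundary", {
  m <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:2, 1] <- NA      # 20% -> removed
  m[1, 2] <- NA        # exactly 10% -> retained
  out <- filter_features_by_missingness(m, 0.10)
  expect_identical(out$removed, "a")
  expect_identical(colnames(out$matrix), c("b", "c"))

  m52 <- matrix(1, 52, 2, dimnames = list(NULL, c("x6", "x5")))
  m52[1:6, 1] <- NA    # 11.5% -> removed
  m52[1:5, 2] <- NA    # 9.6% -> retained
  out52 <- filter_features_by_missingness(m52, 0.10)
  expect_identical(out52$removed, "x6")
})

test_that("patient filter mirrors the feature rule on rows", {
  m <- matrix(1, 4, 20, dimnames = list(sprintf("P%d", 1:4), NULL))
  m[1, 1:3] <- NA      # 15% -> removed
  m[2, 1:2] <- NA      # exactly 10% -> retained
  out <- filter_patients_by_missingness(m, 0.10)
  expect_identical(out$removed, "P1")
  expect_identical(nrow(out$matrix), 3L)
  # complete matrix: nothing removed, and re-application removes nothing
  again <- filter_patients_by_missingness(out$matrix, 0.10)
  expect_length(again$removed, 0)
})

test_that("features containing nonpositive observed values are removed whole", {
  m <- matrix(abs(rnorm(30)) + 1, 10, 3,
              dimnames = list(NULL, c("ok", "neg", "zero")))
  m[4, 2] <- -0.3
  m[7, 3] <- 0
  out <- remove_nonpositive_features(m)
  expect_setequal(out$removed, c("neg", "zero"))
  expect_identical(colnames(out$matrix), "ok")
  expect_identical(remove_nonpositive_features(out$matrix)$removed,
                   character(0))
})

test_that("imputation fills only missing cells and is seed-deterministic", {
  set.seed(42)
  m <- matrix(exp(rnorm(40 * 8)), 40, 8,
              dimnames = list(sprintf("P%d", 1:40), sprintf("f%d", 1:8)))
  holes <- sample(length(m), 30)
  mm <- m; mm[holes] <- NA
  for (method in c("median", "knn", "chained_forest")) {
    cfg <- preprocess_config(imputation_method = method, imputation_seed = 9)
    out <- impute_missing(mm, cfg)
    expect_false(anyNA(out))
    obs <- !is.na(mm)
    expect_identical(out[obs], mm[obs])   # observed cells bit-identical
    expect_identical(out, impute_missing(mm, cfg))
  }
  expect_identical(impute_missing(m, preprocess_config()), m)  # complete
})

test_that("chained-forest imputation beats median imputation on MCAR holes", {
  # correlated features so the forest has signal to exploit
  set.seed(7)
  n <- 60; p <- 8
  base <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(runif(p * 3, 0.5, 1.5), p, 3)
  m <- exp(base %*% t(load) + matrix(rnorm(n * p, sd = 0.3), n, p))
  colnames(m) <- sprintf("f%d", 1:p)
  holes <- sample(length(m), round(0.10 * length(m)))
  mm <- m; mm[holes] <- NA
  rmse <- function(x) sqrt(mean((log(x[holes]) - log(m[holes]))^2))
  forest <- impute_missing(mm, preprocess_config(imputation_method = "chained_forest",
                                                 imputation_seed = 1))
  med <- impute_missing(mm, preprocess_config(imputation_method = "median"))
  expect_lte(rmse(forest), rmse(med))
})

test_that("log + Pareto scaling matches the hand-computed example", {
  m <- cbind(f1 = exp(c(1, 2, 3)))
  out <- log_pareto_scale(m)
  expect_equal(as.numeric(out$matrix), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(out$params$mean, 2)
  expect_equal(out$params$sd, 1)
})

test_that("Pareto scaling centres features and leaves variance equal to log-SD", {
  set.seed(12)
  m <- matrix(exp(rnorm(50 * 6, sd = runif(6, 0.2, 2))), 50, 6,
              dimnames = list(NULL, sprintf("f%d", 1:6)))
  out <- log_pareto_scale(m)
  expect_true(all(abs(colMeans(out$matrix)) < 1e-12))
  expect_equal(apply(out$matrix, 2, var), out$params$sd, tolerance = 1e-10,
               ignore_attr = TRUE)
  # invertibility
  back <- unscale_log_pareto(out$matrix, out$params)
  expect_equal(back, m, tolerance = 1e-10)
  # constant feature errors by name
  expect_error(log_pareto_scale(cbind(const = rep(2, 5))), "const")
})

test_that("the full chain runs in the documented order and reports it", {
  co <- make_cohort(cohort_spec(seed = 21, missing_rate = 0.04))
  pp <- preprocess(co, preprocess_config(imputation_method = "median"))
  rep <- pp$report
  # removed + retained = input roster
  expect_identical(nrow(rep$removed_features) + rep$n_features,
                   ncol(co$metabolites))
  expect_true(all(rep$removed_features$reason %in%
                    c("missingness", "nonpositive")))
  expect_identical(nrow(pp$matrix), nrow(pp$imputed))
  expect_identical(rep$scaling$feature, colnames(pp$matrix))
  expect_true(all(abs(colMeans(pp$matrix)) < 1e-10))
})
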