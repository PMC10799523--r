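# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no binary fixtures.

# Design with exactly orthonormal-scaled columns: X'X = N * I, so the
# penalised solution has the closed form soft_threshold(ols_j, lambda*v_j).
orthonormal_problem <- function(n, p, y = NULL, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * max(p + 1, 2)), n)))[, seq_len(p), drop = FALSE]
  X <- sqrt(n) * Q
  if (is.null(y)) y <- rnorm(n)
  penalized_problem(X, y, standardize = FALSE)
}

# Small random regression problem (standardised).
random_problem <- function(n, p, sparsity = 0, noise = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- numeric(p)
  if (sparsity > 0) beta[seq_len(sparsity)] <- sample(c(-1, 1), sparsity,
                                                      replace = TRUE)
  y <- as.numeric(X %*% beta + rnorm(n, sd = noise))
  penalized_problem(X, y)
}

# Exhaustive two-sided Fisher p for a 2x2 table (minimum-likelihood rule),
# written directly from the hypergeometric point probabilities.
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(d[d <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= ov) from binomial coefficients only.
hyper_tail_oracle <- function(ov, set_size, universe, draws) {
  ks <- ov:min(set_size, draws)
  sum(choose(set_size, ks) * choose(universe - set_size, draws - ks)) /
    choose(universe, draws)
}

# Coefficient table built from the bundled published coefficient roster.
reported_fits <- function() {
  path <- system.file("extdata", "reported_coefficients.csv",
                      package = "metabolasso")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$model), function(d)
    stats::setNames(d$coefficient, d$metabolite))
}

# Proximal-gradient (FISTA) solver for the penalised objective; an
# independent optimisation route used as an oracle against the
# coordinate-descent implementation.
fista_lasso <- function(problem, lambda, iters = 20000) {
  X <- problem$X; y <- problem$y; v <- problem$v; n <- problem$N
  L <- max(svd(X)$d)^2 / n          # Lipschitz constant of the smooth part
  w <- z <- rep(0, problem$p); t0 <- 1
  st <- function(u, g) sign(u) * pmax(abs(u) - g, 0)
  for (i in seq_len(iters)) {
    grad <- -as.numeric(crossprod(X, y - X %*% z)) / n
    w_new <- st(z - grad / L, lambda * v / L)
    t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
    z <- w_new + ((t0 - 1) / t1) * (w_new - w)
    w <- w_new; t0 <- t1
  }
  w
}
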