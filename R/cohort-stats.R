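# Survivor vs non-survivor characterisation: exact tests for discrete
# variables, rank tests for continuous ones, summarised as a comparison table
# (counts for discrete features; median with lower/upper quartile, type-7
# interpolation, for continuous ones).

#' Fisher's exact test
#'
#' Two-sided exact test on an r x c contingency table. For 2 x 2 tables the
#' two-sided p-value follows the minimum-likelihood rule: the sum of
#' hypergeometric point probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. Tables with
#' total count at most `exact_limit` are evaluated by full network
#' enumeration; larger tables fall back to a seeded Monte-Carlo p-value with
#' `B` simulated tables and a reported standard error.
#'
#' @param table matrix of nonnegative integer counts.
#' @param exact_limit largest total count evaluated exactly for r x c tables.
#' @param B Monte-Carlo replicates for large tables.
#' @param seed seed for the Monte-Carlo path.
#' @return list with `p_value`, `method` (`"exact"` or `"monte_carlo"`), and
#'   `mc_se` (`NA` on the exact path).
#' @export
fisher_exact <- function(table, exact_limit = 200L, B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table != round(table)) || any(table < 0))
    abort_fmt("fisher_exact requires nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_fmt("fisher_exact requires all margins > 0")
  storage.mode(table) <- "integer"
  is2x2 <- all(dim(table) == c(2L, 2L))
  if (is2x2 || sum(table) <= exact_limit) {
    p <- fisher.test(table)$p.value
    list(p_value = min(p, 1), method = "exact", mc_se = NA_real_)
  } else {
    p <- with_seed(seed,
                   fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
    list(p_value = p, method = "monte_carlo",
         mc_se = sqrt(p * (1 - p) / B))
  }
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. U is computed from rank sums
#' with midranks for ties. The two-sided p-value is exact (enumeration) when
#' the pooled sample size is at most 20 and there are no ties, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. If every value in both samples is identical the comparison is
#' degenerate: U = n_a * n_b / 2 and p = 1, flagged.
#'
#' @param a,b numeric samples.
#' @return list with `U` (for sample `a`), `p_value`, `method`, `degenerate`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    abort_fmt("mann_whitney requires two nonempty samples")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(pooled) <= 20L)
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx", degenerate = FALSE)
}

#' Group comparison table
#'
#' Compares every requested feature between the two levels of a binary
#' grouping column: discrete features via [fisher_exact()] on the
#' cross-tabulation, continuous features via [mann_whitney()]. Continuous
#' summaries are the median and the lower/upper quartiles under the type-7
#' (linear interpolation) convention. Missing values are dropped per feature
#' unless `include_missing_category` is set, in which case they form their
#' own category for discrete features.
#'
#' @param data a data frame (or a `cohort`, whose clinical table is used).
#' @param grouping name of the binary grouping column.
#' @param features columns to compare; defaults to all except the grouping
#'   column and `patient_id`.
#' @param discrete character vector of features to treat as discrete;
#'   defaults to non-numeric columns plus numeric columns with at most
#'   3 distinct values.
#' @param include_missing_category keep `NA` as its own discrete level.
#' @return a data frame with one row per feature: `feature`, `test_used`,
#'   `p_value`, text summaries per group, and numeric median/quartiles for
#'   continuous features.
#' @export
compare_groups <- function(data, grouping, features = NULL, discrete = NULL,
                           include_missing_category = FALSE) {
  if (inherits(data, "cohort")) data <- data$clinical
  g <- data[[grouping]]
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2L)
    abort_fmt("grouping column '%s' must have exactly 2 levels (found %d)",
              grouping, length(lev))
  lev <- sort(lev)
  if (is.null(features))
    features <- setdiff(names(data), c(grouping, "patient_id"))
  if (is.null(discrete))
    discrete <- features[vapply(features, function(f) {
      x <- data[[f]]
      !is.numeric(x) || length(unique(x[!is.na(x)])) <= 3L
    }, logical(1))]

  rows <- lapply(features, function(f) {
    x <- data[[f]]
    if (f %in% discrete) {
      xx <- as.character(x)
      if (include_missing_category) xx[is.na(xx)] <- "missing"
      keep <- !is.na(xx) & !is.na(g)
      tab <- table(xx[keep], g[keep])
      ft <- fisher_exact(as.matrix(tab))
      summ <- apply(tab, 2, function(cnt)
        paste(sprintf("%s-%d", rownames(tab), cnt), collapse = ", "))
      data.frame(feature = f, test_used = "fisher", p_value = ft$p_value,
                 group1 = summ[as.character(lev[1])],
                 group2 = summ[as.character(lev[2])],
                 median1 = NA_real_, q1_1 = NA_real_, q3_1 = NA_real_,
                 median2 = NA_real_, q1_2 = NA_real_, q3_2 = NA_real_,
                 row.names = NULL)
    } else {
      a <- x[g == lev[1] & !is.na(g)]
      b <- x[g == lev[2] & !is.na(g)]
      mw <- mann_whitney(a, b)
      qa <- quantile(a, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
      qb <- quantile(b, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
      fmtq <- function(q) sprintf("%g (%g-%g)", q[2], q[1], q[3])
      data.frame(feature = f, test_used = "mann_whitney",
                 p_value = mw$p_value,
                 group1 = fmtq(qa), group2 = fmtq(qb),
                 median1 = unname(qa[2]), q1_1 = unname(qa[1]),
                 q3_1 = unname(qa[3]),
                 median2 = unname(qb[2]), q1_2 = unname(qb[1]),
                 q3_2 = unname(qb[3]),
                 row.names = NULL)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "group_levels") <- lev
  out
}
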