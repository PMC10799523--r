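# GMT parsing and the hypergeometric over-representation test.

write_gmt_fixture <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

test_that("GMT parsing builds sets, dedups members, and reports bad lines", {
  path <- write_gmt_fixture(c("A\tset a\tm1\tm2\tm3",
                              "B\tset b\tm2\tm4\tM2"))
  pw <- read_gmt(path)
  expect_length(pw$sets, 2)
  expect_identical(pw$sets$B, c("m2", "m4"))   # duplicate (case) collapsed
  expect_setequal(pw$universe, c("m1", "m2", "m3", "m4"))

  bad <- write_gmt_fixture(c("A\tset a\tm1", "B\tonlydesc"))
  expect_error(read_gmt(bad), "line 2")
  empty <- write_gmt_fixture(character(0))
  expect_error(read_gmt(empty), "empty")
  expect_error(read_gmt(tempfile()), "not found")
})

test_that("feature selection rules mirror the coefficient roster", {
  fits <- reported_fits()
  expect_length(select_features(fits$mortality), 15)
  expect_setequal(select_features(fits$mortality, rule = "top_k", k = 2),
                  c("Isoleucine", "Histidine"))
  expect_identical(select_features(setNames(numeric(3), c("a", "b", "c"))),
                   character(0))
})

test_that("hypergeometric tail matches enumeration from binomial coefficients", {
  # worked example: universe 20, pathway 5, selected 5, overlap 4
  pw <- list(path1 = sprintf("m%d", 1:5))
  universe <- sprintf("m%d", 1:20)
  tab <- ora_test(c("m1", "m2", "m3", "m4", "m20"), pw, universe = universe)
  expect_equal(tab$raw_p, 76 / 15504, tolerance = 1e-12)
  expect_equal(tab$ora_score, -log10(76 / 15504), tolerance = 1e-12)

  # property: all configurations over small universes
  set.seed(1)
  for (i in 1:200) {
    N <- sample(5:25, 1)
    K <- sample(2:N, 1)
    n <- sample(1:N, 1)
    univ <- sprintf("u%02d", seq_len(N))
    sets <- list(s = univ[seq_len(K)])
    sel <- sample(univ, n)
    got <- ora_test(sel, sets, universe = univ, min_size = 2)
    ov <- length(intersect(sel, sets$s))
    expect_equal(got$raw_p, hyper_tail_oracle(ov, K, N, n), tolerance = 1e-12)
    expect_equal(got$overlap, ov)
  }
})

test_that("degenerate selections behave: empty set, pathway = universe", {
  univ <- sprintf("m%d", 1:10)
  sets <- list(all = univ, half = univ[1:5])
  empty <- ora_test(character(0), sets, universe = univ)
  expect_true(all(empty$raw_p == 1))
  expect_true(all(empty$ora_score == 0))
  full <- ora_test(univ[1:4], sets, universe = univ)
  expect_equal(full$raw_p[full$pathway == "all"], 1)
  expect_error(ora_test("nonexistent", sets, universe = univ), "nonexistent")
})

test_that("score and BH adjustment are internally consistent", {
  set.seed(2)
  univ <- sprintf("m%02d", 1:30)
  sets <- lapply(1:6, function(i) sample(univ, sample(3:10, 1)))
  names(sets) <- sprintf("p%d", 1:6)
  tab <- ora_test(sample(univ, 8), sets, universe = univ)
  expect_equal(tab$ora_score, -log10(tab$raw_p), tolerance = 1e-12)
  expect_true(all(tab$adjusted_p >= tab$raw_p - 1e-15))
  expect_true(all(tab$adjusted_p <= 1))
  # BH preserves the raw-p ordering (tab is sorted by raw p)
  expect_true(all(diff(tab$adjusted_p) >= -1e-15))
  expect_equal(tab$adjusted_p, p.adjust(tab$raw_p, "BH"), tolerance = 1e-15)
})

test_that("adding a pathway member to the selection never weakens enrichment", {
  univ <- sprintf("m%d", 1:15)
  sets <- list(s = univ[1:6])
  sel <- univ[c(1, 2, 10)]
  p0 <- ora_test(sel, sets, universe = univ)$raw_p
  p1 <- ora_test(c(sel, univ[3]), sets, universe = univ)$raw_p
  expect_lte(p1, p0)
})

test_that("the bundled synthetic pathway file enriches the amino-acid set", {
  gmt <- system.file("extdata", "synthetic_pathways.gmt",
                     package = "metabolasso")
  pw <- read_gmt(gmt)
  fits <- reported_fits()
  sel <- normalize_feature_name(select_features(fits$mortality))
  sel <- intersect(sel, pw$universe)
  tab <- ora_test(sel, pw)
  aa <- tab[tab$pathway == "aa_metabolism", ]
  expect_lt(aa$raw_p, 0.05)
  expect_gt(aa$overlap, 3)
})
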