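test_that("MDL discretization accepts a clean split and refuses noise", {
  # perfectly separating split: entropy drops 1 bit, MDL accepts one cut
  cuts <- discretize_mdl(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_length(cuts, 1L)
  expect_gt(cuts, 0)
  expect_lt(cuts, 1)

  # single-class labels or constant values: nothing to cut
  expect_length(discretize_mdl(c(1, 2, 3, 4), c(1, 1, 1, 1)), 0L)
  expect_length(discretize_mdl(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0L)

  # alternating labels carry no usable split information
  expect_length(discretize_mdl(1:10, rep(c(0, 1), 5)), 0L)
})

test_that("symmetrical uncertainty hits its defined limits", {
  x <- rep(c(0, 1), each = 10)
  expect_equal(symmetrical_uncertainty(x, x), 1)

  # constructed product distribution: independent
  g <- expand.grid(a = 1:3, b = 1:4)
  expect_equal(symmetrical_uncertainty(g$a, g$b), 0)

  # hand-computed: I(x;y) = 0 for the XOR-free pairing
  expect_equal(symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)

  # zero-entropy variable: defined as 0
  expect_equal(symmetrical_uncertainty(rep(1, 6), rep(c(0, 1), 3)), 0)

  expect_error(symmetrical_uncertainty(1:3, 1:4), "length")
})

test_that("symmetrical uncertainty is symmetric and bounded on random cases", {
  set.seed(33)
  for (i in 1:30) {
    x <- sample(1:4, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    su_xy <- symmetrical_uncertainty(x, y)
    expect_equal(su_xy, symmetrical_uncertainty(y, x))
    expect_gte(su_xy, 0)
    expect_lte(su_xy, 1)
  }
})

test_that("CFS merit follows the k, rcf, rff formula", {
  # build data where the correlations are controlled exactly:
  # f1 determines the class, f2 duplicates f1, f3 independent of both
  y <- rep(c(0, 1), each = 8)
  f1 <- as.numeric(y)
  f3 <- rep(c(0, 1), 8)                     # balanced, independent of y
  fm <- cbind(f1 = f1, f2 = f1, f3 = f3)
  cache <- correlation_cache(fm, y)

  # k = 1 reduces to the feature-class correlation
  expect_equal(cfs_merit("f1", cache), 1)
  expect_equal(cfs_merit("f3", cache), 0)

  # duplicated feature: rcf = 1, rff = 1 -> merit = 2*1/sqrt(2+2) = 1
  expect_equal(cfs_merit(c("f1", "f2"), cache), 1)

  expect_equal(cfs_merit(character(0), cache), 0)
  expect_error(cfs_merit(c("f1", "nope"), cache), "nope")
})

test_that("merit arithmetic matches hand-derived values", {
  # two features each rcf = 0.5: rff = 1 -> 0.5; rff = 0 -> 1/sqrt(2)
  merit <- function(k, rcf, rff) k * rcf / sqrt(k + k * (k - 1) * rff)
  expect_equal(merit(2, 0.5, 1), 0.5)
  expect_equal(merit(2, 0.5, 0), 1 / sqrt(2))
})

test_that("duplicating a feature brings no merit gain over the feature alone", {
  set.seed(12)
  for (i in 1:10) {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    fm <- cbind(a = rnorm(n) + y, b = rnorm(n) + 0.5 * y)
    fm <- cbind(fm, a2 = fm[, "a"])
    cache <- correlation_cache(fm, y)
    # {a, a_copy} has rff = 1, so the merit collapses back to rcf(a)
    expect_equal(cfs_merit(c("a", "a2"), cache), cfs_merit("a", cache))
    expect_lte(cfs_merit(c("a", "a2"), cache),
               cfs_merit("a", cache) + 1e-12)
  }
})

test_that("best-first search attains the exhaustive-search maximum", {
  set.seed(91)
  for (rep in 1:6) {
    n <- 60
    p <- sample(6:10, 1)
    y <- rep(c(0L, 1L), each = n / 2)
    fm <- matrix(rnorm(n * p), n, p)
    informative <- sample(p, 2)
    fm[, informative] <- fm[, informative] + y * sample(c(1, 2, 3), 2, TRUE)
    colnames(fm) <- paste0("f", seq_len(p))
    sel <- best_first_select(fm, y)
    expect_equal(sel$merit, exhaustive_best_merit(fm, y), tolerance = 1e-12)
  }
})

test_that("one determining feature among noise is singled out", {
  set.seed(14)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  fm <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  fm[, 4] <- y * 10 + rnorm(n, sd = 0.01)
  sel <- best_first_select(fm, y)
  expect_equal(sel$names, "f4")
  expect_equal(sel$merit, exhaustive_best_merit(fm, y), tolerance = 1e-12)
})

test_that("pure-noise data yields an empty or null-merit subset", {
  set.seed(2)
  y <- rep(c(0L, 1L), each = 20)
  fm <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("f", 1:8)))
  sel <- best_first_select(fm, y)
  expect_lte(sel$merit, 0.25)
  expect_lte(length(sel$names), 1L)

  # degenerate: all features constant
  fm0 <- matrix(1, 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  sel0 <- best_first_select(fm0, y)
  expect_equal(length(sel0$names), 0L)
  expect_equal(sel0$merit, 0)
})

test_that("adding a pure-noise feature leaves the selected set unchanged", {
  set.seed(77)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  fm <- cbind(sig1 = rnorm(n) + 3 * y, sig2 = rnorm(n) - 2 * y,
              junk = rnorm(n))
  sel_before <- best_first_select(fm, y)
  fm2 <- cbind(fm, junk2 = rnorm(n))
  sel_after <- best_first_select(fm2, y)
  expect_setequal(sel_before$names, sel_after$names)
})

test_that("cross-validated selection is stratified, deterministic, consistent", {
  set.seed(55)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  fm <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  fm[, 1:3] <- fm[, 1:3] + y * 3   # 3 informative + 17 noise features
  res1 <- crossval_select(fm, y, k = 2, seed = 9)
  res2 <- crossval_select(fm, y, k = 2, seed = 9)
  expect_identical(res1$consensus$names, res2$consensus$names)
  expect_identical(lapply(res1$per_fold, `[[`, "names"),
                   lapply(res2$per_fold, `[[`, "names"))

  # informative features appear in both folds' subsets
  for (f in res1$per_fold) {
    expect_true(any(c("f1", "f2", "f3") %in% f$names))
  }
  expect_true(all(res1$consensus$names %in% paste0("f", 1:3)))

  # duplicated data: both folds still see the same strong signal and agree
  # on the informative features (fold contents are random halves, so exact
  # subset identity is not guaranteed — signal membership is)
  fm_dup <- rbind(fm, fm)
  rownames(fm_dup) <- NULL
  res_dup <- crossval_select(fm_dup, c(y, y), k = 2, seed = 1)
  for (f in res_dup$per_fold) {
    expect_true(all(f$names %in% paste0("f", 1:3)))
  }
})
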