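# independent brute-force statistics used as enumeration oracles
brute_F <- function(Y, labels) {
  vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    gm <- tapply(y, labels, mean)
    grand <- mean(y)
    ssb <- sum(table(labels) * (gm - grand)^2)
    ssw <- sum((y - gm[labels])^2)
    k <- length(gm); n <- length(y)
    if (ssw / (n - k) < 1e-12) 0 else (ssb / (k - 1)) / (ssw / (n - k))
  }, 0)
}

brute_t <- function(Y, labels) {
  vapply(seq_len(ncol(Y)), function(j) {
    a <- Y[labels == 1, j]; b <- Y[labels == 2, j]
    se2 <- var(a) / length(a) + var(b) / length(b)
    if (se2 < 1e-12) 0 else abs(mean(a) - mean(b)) / sqrt(se2)
  }, 0)
}

noisy_curves <- function(n, mean_fun = function(t) 4 + 0.002 * t, noise = 0.2,
                         seed = 1, var = "v") {
  tms <- fix_times
  b <- build_basis(c(1, 380), order = 4, at_times = tms)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    penalized_smooth(ferm_series("S", i, var, tms,
                                 mean_fun(tms) + rnorm(8, 0, noise)),
                     b, lambda = 10))
}

test_that("exhaustive 2+2 F-test equals brute-force enumeration of all splits", {
  curves <- noisy_curves(4, seed = 8)
  grid <- seq(1, 380, length.out = 30)
  res <- functional_F_test(curves, c("g1", "g1", "g2", "g2"), grid, n_perm = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 3L)
  Y <- t(vapply(curves, eval_curve, numeric(length(grid)), grid = grid))
  splits <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  maxima <- vapply(splits, function(l) max(brute_F(Y, l)), 0)
  expect_equal(res$statistic_curve, brute_F(Y, c(1, 1, 2, 2)), tolerance = 1e-10)
  expect_equal(sort(res$perm_max), sort(maxima), tolerance = 1e-10)
  expect_equal(res$p_value_max, mean(maxima >= max(maxima[1]) - 1e-12))
})

test_that("exhaustive 2+2 t-test equals brute-force enumeration", {
  curves <- noisy_curves(4, seed = 9)
  grid <- seq(1, 380, length.out = 30)
  res <- functional_t_test(curves[1:2], curves[3:4], grid, n_perm = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 3L)
  Y <- t(vapply(curves, eval_curve, numeric(length(grid)), grid = grid))
  splits <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  maxima <- vapply(splits, function(l) max(brute_t(Y, l)), 0)
  expect_equal(res$statistic_curve, brute_t(Y, c(1, 1, 2, 2)), tolerance = 1e-10)
  expect_equal(sort(res$perm_max), sort(maxima), tolerance = 1e-10)
})

test_that("identical groups give a zero t statistic wherever variances are positive", {
  curves <- noisy_curves(2, seed = 10)
  grid <- seq(1, 380, length.out = 25)
  res <- functional_t_test(curves, curves, grid, n_perm = 100)
  expect_equal(max(res$statistic_curve), 0, tolerance = 1e-10)
  expect_gte(res$p_value_max, 0.9)
})

test_that("clearly separated groups attain the minimum p-value", {
  base <- function(t) 4 + 0.002 * t
  shifted <- function(t) base(t) + 5
  curves <- c(noisy_curves(8, base, noise = 0.05, seed = 12),
              noisy_curves(8, shifted, noise = 0.05, seed = 13))
  grid <- seq(1, 380, length.out = 20)
  res <- functional_F_test(curves, rep(c("a", "b"), each = 8), grid,
                           n_perm = 99, seed = 4)
  expect_false(res$exhaustive)
  expect_equal(res$p_value_max, 1 / (99 + 1))
  expect_gt(res$max_observed, res$max_critical)
})

test_that("derivative delegation: deriv = 0 equals the plain F-test bit for bit", {
  curves <- noisy_curves(6, seed = 14)
  labels <- rep(c("a", "b"), each = 3)
  grid <- seq(1, 380, length.out = 40)
  r1 <- functional_F_test(curves, labels, grid, n_perm = 50, seed = 7)
  r2 <- test_on_derivatives(curves, labels, grid, deriv = 0, n_perm = 50, seed = 7)
  expect_identical(r1, r2)
})

test_that("groups differing only in slope are caught by the derivative test", {
  tms <- fix_times
  b <- build_basis(c(1, 380), order = 4, at_times = tms)
  mk <- function(slope, i, seed) {
    set.seed(seed)
    penalized_smooth(ferm_series("S", i, "v", tms,
                                 4 + slope * (tms - 190) + rnorm(8, 0, 0.05)),
                     b, lambda = 10)
  }
  curves <- c(lapply(1:4, function(i) mk(0.004, i, 20 + i)),
              lapply(1:4, function(i) mk(-0.004, i, 30 + i)))
  labels <- rep(c("up", "down"), each = 4)
  grid <- seq(10, 370, length.out = 50)
  d1 <- test_on_derivatives(curves, labels, grid, deriv = 1, n_perm = 1000, seed = 3)
  expect_true(d1$exhaustive)  # 35 distinct splits
  expect_lte(d1$p_value_max, 0.05)
  # the group mean curves cross near the middle of the domain
  fit <- fit_fanova(curves, labels, 190)
  expect_lt(abs(fit$predicted["up", 1] - fit$predicted["down", 1]), 0.15)
})

test_that("degenerate grid points (zero within-variance) are flagged, not infinite", {
  tms <- fix_times
  b <- build_basis(c(1, 380), order = 4, knots = tms[3:6])
  # interpolating curves that all agree exactly at day 1
  mk <- function(y, i) penalized_smooth(ferm_series("S", i, "v", tms, y), b, lambda = 0)
  y0 <- c(2.71, 3.5, 4, 4.2, 4.3, 4.35, 4.4, 4.42)
  curves <- list(mk(y0, 1), mk(y0 + c(0, 0.1, -0.1, 0.2, 0, 0.1, -0.2, 0), 2),
                 mk(y0 + c(0, -0.1, 0.2, 0, 0.1, -0.1, 0, 0.1), 3),
                 mk(y0 + c(0, 0.2, 0.1, -0.1, 0, 0, 0.1, -0.1), 4))
  res <- functional_F_test(curves, c("a", "a", "b", "b"), tms, n_perm = 100)
  expect_true(res$degenerate_points[1])
  expect_equal(res$statistic_curve[1], 0)
  expect_true(all(is.finite(res$statistic_curve)))
})

test_that("results are deterministic given the seed and p-values never zero", {
  curves <- noisy_curves(10, seed = 15)
  labels <- rep(c("a", "b"), each = 5)
  grid <- seq(1, 380, length.out = 35)
  r1 <- functional_F_test(curves, labels, grid, n_perm = 60, seed = 99)
  r2 <- functional_F_test(curves, labels, grid, n_perm = 60, seed = 99)
  expect_identical(r1, r2)
  r3 <- functional_F_test(curves, labels, grid, n_perm = 60, seed = 100)
  expect_false(identical(r1$perm_max, r3$perm_max))
  expect_gte(r1$p_value_max, 1 / 61)
  # the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(functional_F_test(curves, labels, grid, n_perm = 30, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("input validation: group sizes and permutation counts", {
  curves <- noisy_curves(4, seed = 16)
  expect_error(functional_F_test(curves, c("a", "a", "b", "b"),
                                 1:10, n_perm = 10), "at least 19")
  expect_error(functional_t_test(curves[1], curves[2:4], 1:10), "at least 2")
  expect_error(functional_F_test(curves[1:2], c("a", "b"), 1:10), "at least 3")
})

test_that("fixture pH CT vs RT t-test runs on the daily grid with finite envelopes", {
  ds <- load_fixture("pH")
  sm <- smooth_variable(ds, "pH")
  grid <- seq(1, 380, by = 1)
  res <- functional_t_test(sm$curves[sm$groups == "CT"], sm$curves[sm$groups == "RT"],
                           grid, n_perm = 1000, seed = 1)
  expect_true(res$exhaustive)
  expect_true(all(is.finite(res$pointwise_critical)))
  expect_true(is.finite(res$max_critical) && is.finite(res$p_value_max))
})
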