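make_series <- function(times, values, tr = "A", rep = 1, var = "v") {
  ferm_series(tr, rep, var, times, values)
}

test_that("basis construction follows the knot rules", {
  b <- build_basis(c(1, 380), order = 4, knots = c(15, 38, 52, 80, 137, 250))
  expect_equal(b$nbasis, 10L)
  b2 <- build_basis(c(0, 1), order = 2)
  expect_equal(b2$nbasis, 2L)
  b3 <- build_basis(c(0, 100), order = 4, n_equal = 5)
  expect_equal(b3$knots, c(100 / 6, 200 / 6, 50, 400 / 6, 500 / 6), tolerance = 1e-12)
  b4 <- build_basis(c(1, 380), order = 4, at_times = fix_times)
  expect_equal(b4$knots, c(15, 38, 52, 80, 137, 250))
  expect_error(build_basis(c(1, 1)), "non-degenerate")
  expect_error(build_basis(c(0, 10), knots = c(0, 5)), "strictly inside")
  expect_error(build_basis(c(0, 10), order = 4, at_times = 5), "2 distinct")
})

test_that("lambda = 0 with a saturated basis interpolates exactly", {
  t <- c(1, 3, 7, 12, 20, 31, 45, 60)
  y <- 0.5 + 0.2 * t - 0.01 * t^2 + 2e-4 * t^3
  # 8 points, order 4 + 4 interior knots = 8 basis functions
  b <- build_basis(range(t), order = 4, knots = t[3:6])
  cv <- penalized_smooth(make_series(t, y), b, lambda = 0)
  expect_equal(eval_curve(cv, t), y, tolerance = 1e-8)
})

test_that("a cubic polynomial is reproduced exactly at lambda = 0", {
  t <- seq(0.1, 10, length.out = 9)
  y <- 1 - 2 * t + 0.3 * t^2 - 0.02 * t^3
  b <- build_basis(c(0, 10), order = 4, knots = c(3, 7))
  cv <- penalized_smooth(make_series(t, y), b, lambda = 0)
  expect_equal(eval_curve(cv, t), y, tolerance = 1e-9)
  # derivatives of the polynomial too
  fine <- seq(0.5, 9.5, length.out = 31)
  expect_equal(eval_curve(cv, fine, deriv = 1), -2 + 0.6 * fine - 0.06 * fine^2,
               tolerance = 1e-8)
})

test_that("lambda -> Inf drives the fit to the least-squares straight line", {
  set.seed(3)
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  y <- 3 + 0.004 * t + rnorm(8, 0, 0.4)
  b <- build_basis(c(1, 380), order = 4, at_times = t)
  cv <- penalized_smooth(make_series(t, y), b, lambda = 1e12)
  line <- lm(y ~ t)
  grid <- seq(1, 380, length.out = 101)
  expect_lt(max(abs(eval_curve(cv, grid) - predict(line, data.frame(t = grid)))),
            1e-3 * diff(range(y)))
})

test_that("fixture smoothing fits the observations closely", {
  ds <- load_fixture("yeast")
  sm <- smooth_variable(ds, "yeast")
  s <- get_series(ds, "CC", 1, "yeast")[[1]]
  resid <- s$values - eval_curve(sm$curves[["CC/1"]], s$times)
  expect_lt(sqrt(mean(resid^2)), 0.5)
})

test_that("constant and linear data are reproduced with correct derivatives", {
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  b <- build_basis(c(1, 380), order = 4, at_times = t)
  cv_const <- penalized_smooth(make_series(t, rep(4.2, 8)), b, lambda = 1)
  grid <- seq(1, 380, by = 7)
  expect_equal(eval_curve(cv_const, grid), rep(4.2, length(grid)), tolerance = 1e-8)
  expect_equal(eval_curve(cv_const, grid, deriv = 1), rep(0, length(grid)),
               tolerance = 1e-8)
  cv_lin <- penalized_smooth(make_series(t, 2 + 0.5 * t), b, lambda = 0.01)
  expect_equal(eval_curve(cv_lin, grid, deriv = 1), rep(0.5, length(grid)),
               tolerance = 1e-6)
})

test_that("derivative evaluation matches a central-difference oracle", {
  ds <- load_fixture("pH")
  sm <- smooth_variable(ds, "pH")
  cv <- sm$curves[["CI/1"]]
  grid <- seq(5, 375, length.out = 200)
  h <- 1e-4
  fd1 <- (eval_curve(cv, grid + h) - eval_curve(cv, grid - h)) / (2 * h)
  d1 <- eval_curve(cv, grid, deriv = 1)
  expect_equal(d1, fd1, tolerance = 1e-4)
  fd2 <- (eval_curve(cv, grid + h, deriv = 1) - eval_curve(cv, grid - h, deriv = 1)) / (2 * h)
  expect_equal(eval_curve(cv, grid, deriv = 2), fd2, tolerance = 1e-4)
})

test_that("integration is exact for closed forms and matches fine trapezoid", {
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  b <- build_basis(c(1, 380), order = 4, at_times = t)
  cv_const <- penalized_smooth(make_series(t, rep(3, 8)), b, lambda = 1)
  expect_equal(integrate_curve(cv_const, 1, 380), 379 * 3, tolerance = 1e-8)
  # the fitted curve spans the full [0, 10] basis domain even though the
  # observations start later; an interpolated line integrates in closed form
  t2 <- seq(0.5, 10, length.out = 8)
  b2 <- build_basis(c(0, 10), order = 4, knots = t2[3:6])
  cv_lin <- penalized_smooth(make_series(t2, 2 + 0.5 * t2), b2, lambda = 0)
  expect_equal(integrate_curve(cv_lin, 0, 10), 45, tolerance = 1e-8)
  # quadrature oracle on a genuinely curved fit
  ds <- load_fixture("pH")
  cv <- smooth_variable(ds, "pH")$curves[["CC/1"]]
  g <- seq(1, 380, length.out = 1e5)
  trap <- sum(diff(g) * (head(eval_curve(cv, g), -1) + tail(eval_curve(cv, g), -1)) / 2)
  expect_equal(integrate_curve(cv, 1, 380), trap, tolerance = 1e-6)
  expect_error(integrate_curve(cv, 100, 100), "a < b")
})

test_that("smoothing is linear in the data", {
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  b <- build_basis(c(1, 380), order = 4, at_times = t)
  set.seed(11)
  y1 <- rnorm(8, 4); y2 <- rnorm(8, 1)
  c1 <- penalized_smooth(make_series(t, y1), b, lambda = 10)$coefficients
  c2 <- penalized_smooth(make_series(t, y2), b, lambda = 10)$coefficients
  c12 <- penalized_smooth(make_series(t, y1 + y2), b, lambda = 10)$coefficients
  expect_equal(c12, c1 + c2, tolerance = 1e-8)
})

test_that("roughness of the fit is non-increasing in lambda", {
  ds <- load_fixture("acidity")
  s <- get_series(ds, "CI", 1, "acidity")[[1]]
  b <- build_basis(c(1, 380), order = 4, at_times = s$times)
  R <- penalty_matrix(b)
  rough <- vapply(10^seq(-2, 6, by = 1), function(lam) {
    cf <- penalized_smooth(s, b, lambda = lam)$coefficients
    drop(t(cf) %*% R %*% cf)
  }, 0)
  expect_true(all(diff(rough) <= 1e-10 * max(rough)))
})

test_that("GCV selection is deterministic and picks a grid member", {
  ds <- load_fixture("pH")
  sl <- get_series(ds, variable = "pH")
  b <- build_basis(c(1, 380), order = 4, at_times = fix_times)
  sel1 <- select_lambda(sl, b)
  sel2 <- select_lambda(sl, b)
  expect_identical(sel1$lambda, sel2$lambda)
  expect_true(sel1$lambda %in% sel1$grid)
})

test_that("singular systems and domain violations raise errors", {
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  b <- build_basis(c(1, 380), order = 4, at_times = t)  # 10 basis > 8 points
  s <- make_series(t, rnorm(8))
  expect_error(penalized_smooth(s, b, lambda = 0), "singular")
  cv <- penalized_smooth(s, b, lambda = 1)
  expect_error(eval_curve(cv, 381), "extrapolation")
  expect_error(eval_curve(cv, 100, deriv = 3), "derivative")
  expect_error(penalized_smooth(make_series(c(1, 2), 1:2), b), "3 non-missing")
})

test_that("missing observations are dropped while the curve spans the domain", {
  t <- c(1, 15, 38, 52, 80, 137, 250, 380)
  y <- c(NA, 5.26, 4.97, 5.12, 4.46, 5.73, 4.81, 1.78)
  b <- build_basis(c(1, 380), order = 4, at_times = t)
  cv <- penalized_smooth(ferm_series("CI", 2, "yeast", t, y), b, lambda = 10)
  expect_true(all(is.finite(eval_curve(cv, seq(1, 380, by = 1)))))
})

test_that("curves serialize to JSON and back exactly", {
  ds <- load_fixture("pH")
  cv <- smooth_variable(ds, "pH")$curves[["CT/2"]]
  js <- curve_to_json(cv)
  cv2 <- curve_from_json(js)
  expect_identical(cv2$coefficients, cv$coefficients)
  expect_identical(cv2$basis$knots, cv$basis$knots)
  expect_identical(cv2$lambda_used, cv$lambda_used)
  grid <- seq(1, 380, length.out = 50)
  expect_identical(eval_curve(cv2, grid), eval_curve(cv, grid))
})
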