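# Penalized B-spline smoothing: turns a sparse observed series into a
# functional curve evaluable at any time and derivative order.
#
# The fitted curve f(t) = sum_k c_k B_k(t) minimizes
#   sum_j (y_j - f(t_j))^2 + lambda * int f''(t)^2 dt
# over the span of a B-spline basis. The second-derivative penalty keeps
# the curve twice-differentiable in a controlled way, which matters here
# because downstream analyses compare first and second derivatives of
# fermentation curves across treatments.

#' Build a B-spline basis specification
#'
#' @param domain Length-2 numeric `c(t_min, t_max)` in days.
#' @param order Spline order (polynomial degree + 1); default 4 (cubic).
#' @param knots Ascending interior knots strictly inside the domain.
#'   Mutually exclusive with `n_equal`.
#' @param n_equal If given, place this many equally spaced interior knots.
#' @param at_times If given (a vector of observation times), interior knots
#'   are placed at the interior observation times (all but the first and
#'   last distinct times).
#' @return Object of class `bspline_basis`: `domain`, `order`, `knots`
#'   (interior), `nbasis = order + length(knots)`.
#' @export
build_basis <- function(domain, order = 4, knots = NULL, n_equal = NULL,
                        at_times = NULL) {
  domain <- as.numeric(domain)
  if (length(domain) != 2 || diff(domain) <= 0) stop("domain must be non-degenerate c(t_min, t_max)")
  if (order < 2) stop("order must be >= 2")
  if (!is.null(at_times)) {
    ts <- sort(unique(as.numeric(at_times)))
    if (length(ts) < 2) stop("need at least 2 distinct times for knot placement")
    knots <- ts[ts > domain[1] & ts < domain[2]]
    knots <- setdiff(knots, range(ts))
  } else if (!is.null(n_equal)) {
    knots <- domain[1] + diff(domain) * seq_len(n_equal) / (n_equal + 1)
  }
  knots <- as.numeric(knots)
  if (length(knots)) {
    if (any(diff(knots) <= 0)) stop("interior knots must be strictly ascending")
    if (min(knots) <= domain[1] || max(knots) >= domain[2])
      stop("interior knots must lie strictly inside the domain")
  }
  structure(list(domain = domain, order = as.integer(order), knots = knots,
                 nbasis = as.integer(order + length(knots))),
            class = "bspline_basis")
}

full_knots <- function(basis) {
  c(rep(basis$domain[1], basis$order), basis$knots, rep(basis$domain[2], basis$order))
}

#' Evaluate the basis matrix
#'
#' @param basis A `bspline_basis`.
#' @param x Evaluation times within the domain.
#' @param deriv Derivative order (0 to `order - 2`).
#' @return Matrix `length(x)` x `nbasis`.
#' @export
eval_basis <- function(basis, x, deriv = 0) {
  x <- as.numeric(x)
  if (any(x < basis$domain[1] - 1e-10 | x > basis$domain[2] + 1e-10))
    stop("evaluation point outside the basis domain [", basis$domain[1], ", ",
         basis$domain[2], "]; no extrapolation")
  if (deriv > basis$order - 2)
    stop("derivative order ", deriv, " not supported by order-", basis$order, " basis")
  x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  splines::splineDesign(full_knots(basis), x, ord = basis$order,
                        derivs = rep(deriv, length(x)), outer.ok = FALSE)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Piecewise Gauss-Legendre quadrature over the knot spans; with npts high
# enough this integrates products of spline pieces exactly.
span_quadrature <- function(basis, npts) {
  brk <- unique(c(basis$domain[1], basis$knots, basis$domain[2]))
  gl <- gauss_legendre(npts)
  nodes <- weights <- numeric(0)
  for (i in seq_len(length(brk) - 1)) {
    h <- (brk[i + 1] - brk[i]) / 2
    nodes <- c(nodes, brk[i] + h * (gl$x + 1))
    weights <- c(weights, gl$w * h)
  }
  list(nodes = nodes, weights = weights)
}

#' Roughness penalty matrix
#'
#' Computes `R[k, l] = int B_k''(t) B_l''(t) dt` over the domain by
#' piecewise Gauss-Legendre quadrature, exact for polynomial pieces.
#'
#' @param basis A `bspline_basis` with `order >= 3`.
#' @return Symmetric `nbasis` x `nbasis` matrix.
#' @export
penalty_matrix <- function(basis) {
  if (basis$order < 3) return(matrix(0, basis$nbasis, basis$nbasis))
  # integrand degree 2*(order-3); order-1 points are always enough
  q <- span_quadrature(basis, max(basis$order - 1, 2))
  B2 <- eval_basis(basis, q$nodes, deriv = 2)
  crossprod(B2 * sqrt(q$weights))
}

#' Penalized least-squares smooth of one series
#'
#' Fits the basis coefficients minimizing the penalized residual sum of
#' squares; missing observations are dropped from the fit while the curve
#' stays defined on the whole basis domain.
#'
#' @param series A [ferm_series()] with at least 3 non-missing points.
#' @param basis A [build_basis()] specification covering the series.
#' @param lambda Non-negative roughness penalty weight on
#'   `int f''(t)^2 dt`. With `lambda = 0` the basis must not exceed the
#'   number of non-missing points.
#' @param gcv If `TRUE`, also report the generalized cross-validation
#'   score of the fit.
#' @return Object of class `fcurve`: `basis`, `coefficients`,
#'   `lambda_used`, `gcv_score` (or `NA`), `source` (series key), `df`
#'   (effective degrees of freedom).
#' @export
penalized_smooth <- function(series, basis, lambda = 0, gcv = FALSE) {
  ok <- !series$missing & !is.na(series$values)
  if (sum(ok) < 3) stop("need at least 3 non-missing points to smooth")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  t_ok <- series$times[ok]
  y <- series$values[ok]
  B <- eval_basis(basis, t_ok)
  R <- if (lambda > 0) penalty_matrix(basis) else matrix(0, basis$nbasis, basis$nbasis)
  M <- crossprod(B) + lambda * R
  if (rcond(M) < 1e-14)
    stop("singular smoothing system: use lambda > 0 or a basis with at most ",
         length(y), " functions")
  cf <- solve(M, crossprod(B, y))
  score <- NA_real_
  df <- sum(diag(B %*% solve(M, t(B))))
  if (gcv) {
    n <- length(y)
    rss <- sum((y - B %*% cf)^2)
    score <- if (n - df > 1e-8) n * rss / (n - df)^2 else Inf
  }
  structure(list(basis = basis, coefficients = as.numeric(cf),
                 lambda_used = lambda, gcv_score = score, df = df,
                 source = paste(series$treatment, series$replicate,
                                series$variable, sep = "/")),
            class = "fcurve")
}

#' @export
print.fcurve <- function(x, ...) {
  cat(sprintf("<fcurve> %s: %d basis functions (order %d), lambda = %g, df = %.2f\n",
              x$source, x$basis$nbasis, x$basis$order, x$lambda_used, x$df))
  invisible(x)
}

#' Evaluate a functional curve
#'
#' @param curve An `fcurve`.
#' @param grid Times within the curve's domain.
#' @param deriv Derivative order 0, 1 or 2 (up to `order - 2`).
#' @return Numeric vector of `f^(deriv)(t)` values.
#' @export
eval_curve <- function(curve, grid, deriv = 0) {
  drop(eval_basis(curve$basis, grid, deriv) %*% curve$coefficients)
}

#' @rdname eval_curve
#' @param object An `fcurve`.
#' @param ... Ignored.
#' @export
predict.fcurve <- function(object, grid, deriv = 0, ...) {
  eval_curve(object, grid, deriv)
}

#' Integrate a functional curve
#'
#' Exact piecewise-polynomial integration of `f(t)` over `[a, b]` by
#' Gauss-Legendre quadrature on each knot span (exact for the spline's
#' polynomial degree).
#'
#' @param curve An `fcurve`.
#' @param a,b Integration limits within the domain, `a < b`.
#' @return The integral, a single number.
#' @export
integrate_curve <- function(curve, a, b) {
  basis <- curve$basis
  if (a >= b) stop("need a < b")
  if (a < basis$domain[1] - 1e-10 || b > basis$domain[2] + 1e-10)
    stop("integration limits outside the curve domain")
  brk <- unique(c(a, basis$knots[basis$knots > a & basis$knots < b], b))
  gl <- gauss_legendre(max(ceiling(basis$order / 2) + 1, 2))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    h <- (brk[i + 1] - brk[i]) / 2
    x <- brk[i] + h * (gl$x + 1)
    total <- total + sum(gl$w * h * eval_curve(curve, x))
  }
  total
}

#' Select a shared roughness penalty by generalized cross-validation
#'
#' Evaluates each candidate `lambda` on every series and picks the grid
#' member minimizing the summed GCV score, so all series of a variable are
#' smoothed with one penalty and their curves stay comparable.
#'
#' @param series_list List of [ferm_series()] (each with >= 3 usable points).
#' @param basis Shared [build_basis()].
#' @param grid Candidate lambdas; default 33 log-spaced values in
#'   `[1e-2, 1e6]`.
#' @return List: `lambda` (the selected grid member), `scores` (summed GCV
#'   per candidate), `grid`.
#' @export
select_lambda <- function(series_list, basis,
                          grid = 10^seq(-2, 6, length.out = 33)) {
  scores <- vapply(grid, function(lam) {
    sum(vapply(series_list, function(s)
      penalized_smooth(s, basis, lambda = lam, gcv = TRUE)$gcv_score, 0))
  }, 0)
  list(lambda = grid[which.min(scores)], scores = scores, grid = grid)
}

#' Smooth every series of one variable with a shared basis and penalty
#'
#' Convenience wrapper for the standard pipeline: build a cubic basis with
#' interior knots at the interior observation times, select one lambda by
#' GCV across all series of the variable, and smooth each series.
#'
#' @param dataset A [ferm_dataset()].
#' @param variable Variable name to smooth.
#' @param basis Optional basis; default order-4 with knots at the interior
#'   observation times of the first usable series.
#' @param lambda Either `"gcv"` (default: shared GCV selection) or a fixed
#'   non-negative number.
#' @param lambda_grid Grid for GCV selection (see [select_lambda()]).
#' @return List: `curves` (named list of `fcurve`, keyed
#'   `treatment/replicate`), `groups` (treatment per curve), `basis`,
#'   `lambda`.
#' @export
smooth_variable <- function(dataset, variable, basis = NULL, lambda = "gcv",
                            lambda_grid = 10^seq(-2, 6, length.out = 33)) {
  sl <- get_series(dataset, variable = variable)
  sl <- Filter(function(s) n_usable(s) >= 3, sl)
  if (!length(sl)) stop("no smoothable series for variable '", variable, "'")
  if (is.null(basis))
    basis <- build_basis(dataset$domain, order = 4, at_times = sl[[1]]$times)
  if (identical(lambda, "gcv"))
    lambda <- select_lambda(sl, basis, lambda_grid)$lambda
  curves <- lapply(sl, penalized_smooth, basis = basis, lambda = lambda)
  names(curves) <- vapply(sl, function(s) paste(s$treatment, s$replicate, sep = "/"), "")
  list(curves = curves,
       groups = vapply(sl, `[[`, "", "treatment"),
       basis = basis, lambda = lambda)
}

#' Serialize a curve to JSON
#'
#' Round-trip exact: [curve_from_json()] on the output reproduces the
#' curve's basis, coefficients and penalty.
#'
#' @param curve An `fcurve`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
curve_to_json <- function(curve, path = NULL) {
  # doubles carried as %.17g strings so the round trip is bit-exact
  num <- function(x) sprintf("%.17g", x)
  obj <- list(domain = num(curve$basis$domain), order = curve$basis$order,
              knots = num(curve$basis$knots), coefficients = num(curve$coefficients),
              lambda_used = num(curve$lambda_used), source = curve$source)
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname curve_to_json
#' @param json A JSON string or file path produced by [curve_to_json()].
#' @export
curve_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "")
  obj <- jsonlite::fromJSON(json)
  basis <- build_basis(obj$domain, order = obj$order, knots = obj$knots)
  structure(list(basis = basis, coefficients = as.numeric(obj$coefficients),
                 lambda_used = as.numeric(obj$lambda_used), gcv_score = NA_real_,
                 df = NA_real_, source = as.character(obj$source)),
            class = "fcurve")
}
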