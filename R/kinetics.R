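# Asymptotic-exponential acidification kinetics:
#   y(x) = a + b * (1 - exp(-c * x))
# a is the value at x = 0, a + b the asymptote, and c (days^-1) the rate
# at which the asymptote is approached. Fitted to the pooled replicate
# observations of one treatment by nonlinear least squares.

kinetic_rhs <- function(x, a, b, c) a + b * (1 - exp(-c * x))

#' Fit the asymptotic exponential model to pooled series
#'
#' Pools the non-missing observations of the supplied series (typically
#' both replicates of one treatment) and fits
#' `y = a + b * (1 - exp(-c x))` by nonlinear least squares
#' (Levenberg-Marquardt) with deterministic starting values
#' `a0 = min(y)`, `b0 = max(y) - min(y)`, `c0 = 0.05`. Standard errors
#' are the asymptotic Jacobian-based ones,
#' `sqrt(RSS/(n-3) * diag((J'J)^-1))`. A fit that stalls or hits the
#' iteration cap is returned with `converged = FALSE` rather than an
#' error, so unstable treatments are reported with their diagnostics.
#'
#' @param series_pool List of [ferm_series()] (or a single series) for
#'   one treatment and variable.
#' @param c0 Starting rate; default 0.05 days^-1.
#' @param maxiter Iteration cap; default 500.
#' @return Object of class `kinetic_fit`: `treatment`, `variable`,
#'   `coefficients` (a, b, c), `se` (se_a, se_b, se_c), `rss`,
#'   `converged`, `n_obs`, `message`.
#' @export
fit_kinetic <- function(series_pool, c0 = 0.05, maxiter = 500) {
  if (inherits(series_pool, "ferm_series")) series_pool <- list(series_pool)
  x <- unlist(lapply(series_pool, function(s) s$times[!s$missing & !is.na(s$values)]))
  y <- unlist(lapply(series_pool, function(s) s$values[!s$missing & !is.na(s$values)]))
  if (length(x) < 4) stop("need at least 4 pooled non-missing points (3 parameters)")
  if (diff(range(y)) == 0) stop("all responses equal: b is unidentifiable")
  treatment <- paste(unique(vapply(series_pool, `[[`, "", "treatment")), collapse = "+")
  variable <- paste(unique(vapply(series_pool, `[[`, "", "variable")), collapse = "+")
  start <- list(a = min(y), b = max(y) - min(y), c = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * (1 - exp(-c * x)),
                      data = data.frame(x = x, y = y), start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(treatment = treatment, variable = variable,
                          coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_),
                          se = c(se_a = NA_real_, se_b = NA_real_, se_c = NA_real_),
                          rss = NA_real_, converged = FALSE, n_obs = length(x),
                          message = conditionMessage(fit)),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  info <- fit$convInfo
  converged <- isTRUE(info$isConv) && all(is.finite(cf)) && all(is.finite(se))
  structure(list(treatment = treatment, variable = variable,
                 coefficients = c(a = unname(cf["a"]), b = unname(cf["b"]),
                                  c = unname(cf["c"])),
                 se = c(se_a = unname(se["a"]), se_b = unname(se["b"]),
                        se_c = unname(se["c"])),
                 rss = sum(stats::resid(fit)^2), converged = converged,
                 n_obs = length(x), message = info$stopMessage),
            class = "kinetic_fit")
}

#' Predict from a kinetic fit
#'
#' @param fit A converged [fit_kinetic()] result.
#' @param times Times (days) at which to evaluate the model.
#' @return Numeric vector of model values.
#' @export
predict_kinetic <- function(fit, times) {
  if (!isTRUE(fit$converged)) stop("cannot predict from an unconverged kinetic fit")
  cf <- fit$coefficients
  kinetic_rhs(times, cf["a"], cf["b"], cf["c"])
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cf <- x$coefficients; se <- x$se
  cat(sprintf("<kinetic_fit> %s / %s: y = a + b(1 - exp(-c x)), n = %d%s\n",
              x$treatment, x$variable, x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  a = %.4g +/- %.2g; b = %.4g +/- %.2g; c = %.4g +/- %.2g days^-1\n",
              cf["a"], se["se_a"], cf["b"], se["se_b"], cf["c"], se["se_c"]))
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Kinetic fits for every treatment of a variable
#'
#' @param dataset A [ferm_dataset()].
#' @param variable Variable fitted (default `"pH"`).
#' @param ... Passed to [fit_kinetic()].
#' @return Data frame with one row per treatment: parameters, SEs, RSS,
#'   convergence flag.
#' @export
kinetic_table <- function(dataset, variable = "pH", ...) {
  trs <- unique(vapply(get_series(dataset, variable = variable), `[[`, "", "treatment"))
  rows <- lapply(trs, function(tr) {
    f <- fit_kinetic(get_series(dataset, treatment = tr, variable = variable), ...)
    data.frame(treatment = tr, a = f$coefficients["a"], se_a = f$se["se_a"],
               b = f$coefficients["b"], se_b = f$se["se_b"],
               c = f$coefficients["c"], se_c = f$se["se_c"],
               rss = f$rss, n_obs = f$n_obs, converged = f$converged,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
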