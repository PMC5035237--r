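# Seeded generator of fermentation-like datasets with known ground truth,
# used to calibrate the permutation tests and to check parameter recovery.
# Two mean-shape families mirror the study's variables: the asymptotic
# exponential (monotone-saturating acidification, pH-like) and a smooth
# rise-plateau-decline arc (yeast-population-like); arbitrary tabulated
# shapes are linearly interpolated. Observation noise is i.i.d. Gaussian.

#' Asymptotic exponential mean value
#'
#' `a + b * (1 - exp(-c * t))` — the acidification kinetics shape.
#'
#' @param t Times (days).
#' @param a,b,c Intercept, overall change, rate (days^-1).
#' @return Numeric vector.
#' @export
kinetic_mean <- function(t, a, b, c) a + b * (1 - exp(-c * t))

#' Rise-plateau-decline arc
#'
#' Smooth unimodal trajectory mimicking a microbial growth curve: a
#' quadratic rise reaching exactly `peak_level` at `peak_time` (initial
#' slope `rise_rate`), then a decline whose slope tends to
#' `-decline_rate`; the two pieces join with a continuous first
#' derivative. With `decline_rate = 0` the curve is non-decreasing.
#'
#' @param t Times (days), positive.
#' @param rise_rate Initial upward slope (units/day), > 0.
#' @param peak_level Value attained at `peak_time`.
#' @param peak_time Day of the peak, > 0.
#' @param decline_rate Asymptotic downward slope after the peak, >= 0.
#' @return Numeric vector.
#' @export
yeast_arc <- function(t, rise_rate, peak_level, peak_time, decline_rate) {
  if (rise_rate <= 0) stop("rise_rate must be positive")
  if (decline_rate < 0) stop("decline_rate must be non-negative")
  if (peak_time <= 0) stop("peak_time must be positive")
  ifelse(t <= peak_time,
         peak_level - (rise_rate * peak_time / 2) * (1 - t / peak_time)^2,
         peak_level - decline_rate * (t - peak_time)^2 / ((t - peak_time) + peak_time))
}

mean_function <- function(mf) {
  if (is.function(mf)) return(mf)
  if (!is.list(mf) || is.null(mf$type)) stop("mean_function must be a function or a typed list")
  switch(mf$type,
         kinetic = function(t) kinetic_mean(t, mf$a, mf$b, mf$c),
         yeast_arc = function(t) yeast_arc(t, mf$rise_rate, mf$peak_level,
                                           mf$peak_time, mf$decline_rate),
         tabulated = {
           stopifnot(length(mf$times) == length(mf$values))
           function(t) stats::approx(mf$times, mf$values, xout = t, rule = 2)$y
         },
         stop("unknown mean_function type '", mf$type, "'"))
}

#' Specify a synthetic fermentation dataset
#'
#' @param treatments Named list: one mean function per treatment label.
#'   Each entry is either a function of time or a typed list —
#'   `list(type = "kinetic", a, b, c)`,
#'   `list(type = "yeast_arc", rise_rate, peak_level, peak_time, decline_rate)`,
#'   or `list(type = "tabulated", times, values)`.
#' @param n_replicates Replicates per treatment; default 2, matching the
#'   study design.
#' @param times Observation days; default the study's sampling schedule
#'   `c(1, 15, 38, 52, 80, 137, 250, 380)`.
#' @param noise_sd Gaussian observation noise SD (value units), >= 0.
#' @param variable Variable name stamped on the series.
#' @param missing_policy `list(type = "none")` (default) or
#'   `list(type = "drop_first_k", k, prob)`: each series independently has
#'   its first `k` observations flagged missing with probability `prob`
#'   (emulating unquantified early plate counts).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(treatments, n_replicates = 2,
                           times = c(1, 15, 38, 52, 80, 137, 250, 380),
                           noise_sd = 0.2, variable = "synthetic",
                           missing_policy = list(type = "none"), seed = 1) {
  if (is.null(names(treatments)) || any(names(treatments) == ""))
    stop("treatments must be a named list (label -> mean function)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(times) <= 0)) stop("observation times must be ascending")
  fns <- lapply(treatments, mean_function)   # validates types up front
  structure(list(treatments = treatments, mean_fns = fns,
                 n_replicates = as.integer(n_replicates),
                 times = as.numeric(times), noise_sd = noise_sd,
                 variable = variable, missing_policy = missing_policy,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' Draws `value(t) = mean_function(t) + N(0, noise_sd)` independently per
#' observation, applies the missing-value policy, and returns a validated
#' [ferm_dataset()]. Deterministic given the spec's seed; the caller's
#' RNG state is preserved.
#'
#' @param spec A [synthetic_spec()].
#' @return A `ferm_dataset`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  series <- list()
  for (tr in names(spec$treatments)) {
    f <- spec$mean_fns[[tr]]
    for (r in seq_len(spec$n_replicates)) {
      vals <- f(spec$times) + stats::rnorm(length(spec$times), 0, spec$noise_sd)
      miss <- rep(FALSE, length(spec$times))
      mp <- spec$missing_policy
      if (identical(mp$type, "drop_first_k") &&
          stats::runif(1) < mp$prob) {
        miss[seq_len(min(mp$k, length(miss)))] <- TRUE
      }
      series[[length(series) + 1]] <-
        ferm_series(tr, r, spec$variable, spec$times, vals, miss)
    }
  }
  ferm_dataset(series, domain = range(spec$times))
}
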