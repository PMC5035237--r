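# Area-under-curve analysis: one number per replicate (the area below its
# observed time course), compared across treatments by one-way ANOVA with
# Fisher LSD pairwise comparisons. The raw trapezoid is the default area
# because it reproduces the fixture's published pH and acidity treatment
# means exactly after rounding; areas from smoothed curves are available
# as an alternative.

#' Trapezoid area under an observed series
#'
#' Straight-line (trapezoidal) integration over the non-missing
#' observations; missing points are skipped, so integration runs from the
#' first to the last usable observation.
#'
#' @param series A [ferm_series()] with at least 2 non-missing points.
#' @return The area (value units x days).
#' @export
trapezoid_area <- function(series) {
  ok <- !series$missing & !is.na(series$values)
  if (sum(ok) < 2) stop("need at least 2 non-missing points for a trapezoid area")
  t <- series$times[ok]
  y <- series$values[ok]
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Area under a smoothed curve
#'
#' Delegates to [integrate_curve()]; exposed as the alternative
#' area-under-curve method for [auc_anova()].
#'
#' @param curve An `fcurve`.
#' @param a,b Integration limits; default the curve's full domain.
#' @return The area.
#' @export
smoothed_area <- function(curve, a = curve$basis$domain[1], b = curve$basis$domain[2]) {
  integrate_curve(curve, a, b)
}

#' Area-under-curve ANOVA with Fisher LSD comparisons
#'
#' Computes one area per replicate series of the requested variable,
#' averages by treatment (mean +/- SE), runs a one-way ANOVA on the
#' per-replicate areas, and performs all pairwise Fisher least significant
#' difference comparisons: a pair differs significantly when
#' `|diff of means| >= t(1-alpha/2, df_within) * sqrt(MS_within * (1/n_i + 1/n_j))`.
#'
#' @param dataset A [ferm_dataset()].
#' @param variable Variable analyzed.
#' @param method `"raw_trapezoid"` (default) or `"smoothed_integral"`
#'   (areas from shared-GCV smoothed curves over the dataset domain).
#' @param se_convention `"sample"` (sd/sqrt(n), default) or
#'   `"population"` (population sd/sqrt(n), which for n = 2 equals
#'   `|diff|/(2*sqrt(2))`).
#' @param alpha LSD level; default 0.05.
#' @param lambda Passed to [smooth_variable()] when
#'   `method = "smoothed_integral"`.
#' @return Object of class `auc_analysis`: `variable`, `method`, `areas`
#'   (data frame treatment/replicate/area), `group_means`, `group_ses`,
#'   `anova` (list `ss_between`, `ss_within`, `df_between`, `df_within`,
#'   `F`, `p`), `lsd` (data frame `pair`, `diff_of_means`,
#'   `lsd_threshold`, `p`, `significant`), `se_convention`.
#' @export
auc_anova <- function(dataset, variable,
                      method = c("raw_trapezoid", "smoothed_integral"),
                      se_convention = c("sample", "population"),
                      alpha = 0.05, lambda = "gcv") {
  method <- match.arg(method)
  se_convention <- match.arg(se_convention)
  sl <- get_series(dataset, variable = variable)
  if (!length(sl)) stop("no series for variable '", variable, "'")
  if (method == "raw_trapezoid") {
    areas <- vapply(sl, trapezoid_area, 0)
    tr <- vapply(sl, `[[`, "", "treatment")
    rp <- vapply(sl, function(s) s$replicate, 0L)
  } else {
    sm <- smooth_variable(dataset, variable, lambda = lambda)
    areas <- vapply(sm$curves, smoothed_area, 0)
    tr <- sm$groups
    rp <- as.integer(sub(".*/", "", names(sm$curves)))
  }
  df <- data.frame(treatment = tr, replicate = rp, area = areas,
                   stringsAsFactors = FALSE)
  sizes <- table(df$treatment)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 treatments with at least 2 replicates each")
  means <- c(tapply(df$area, df$treatment, mean))
  sds <- c(tapply(df$area, df$treatment, stats::sd))
  if (se_convention == "population")
    sds <- sds * sqrt((as.numeric(sizes) - 1) / as.numeric(sizes))
  ses <- sds / sqrt(as.numeric(sizes))
  fit <- stats::lm(area ~ treatment, data = df)
  an <- stats::anova(fit)
  msw <- an["Residuals", "Mean Sq"]
  dfw <- an["Residuals", "Df"]
  lev <- names(means)
  pairs <- utils::combn(lev, 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a1 <- pairs[1, j]; a2 <- pairs[2, j]
    # larger group mean first, matching the usual reporting orientation
    if (means[a2] > means[a1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
    d <- means[a1] - means[a2]
    sed <- sqrt(msw * (1 / sizes[[a1]] + 1 / sizes[[a2]]))
    thr <- stats::qt(1 - alpha / 2, dfw) * sed
    data.frame(pair = paste(a1, "vs", a2), diff_of_means = unname(d),
               lsd_threshold = unname(thr),
               p = unname(2 * stats::pt(-abs(d / sed), dfw)),
               significant = unname(d >= thr), stringsAsFactors = FALSE)
  }))
  structure(list(
    variable = variable, method = method, areas = df,
    group_means = means, group_ses = ses, se_convention = se_convention,
    anova = list(ss_between = an["treatment", "Sum Sq"],
                 ss_within = an["Residuals", "Sum Sq"],
                 df_between = an["treatment", "Df"], df_within = dfw,
                 F = an["treatment", "F value"],
                 p = an["treatment", "Pr(>F)"]),
    lsd = lsd, alpha = alpha),
    class = "auc_analysis")
}

#' @export
print.auc_analysis <- function(x, ...) {
  cat(sprintf("<auc_analysis> %s areas (%s), %d treatments\n",
              x$variable, x$method, length(x$group_means)))
  for (g in names(x$group_means))
    cat(sprintf("  %-4s %8.1f (SE %.1f)\n", g, x$group_means[g], x$group_ses[g]))
  cat(sprintf("  one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  sig <- x$lsd[x$lsd$significant, "pair"]
  cat("  LSD-significant pairs:", if (length(sig)) paste(sig, collapse = "; ") else "none", "\n")
  invisible(x)
}
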