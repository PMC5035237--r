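# Pointwise descriptive statistics across a set of functional curves.

#' Pointwise summary of a set of curves
#'
#' Evaluates every curve on a common grid and computes, at each grid
#' point, the cross-curve mean, standard deviation, minimum and maximum —
#' the functional analogue of per-time-point descriptive statistics.
#'
#' @param curves List of [penalized_smooth()] curves whose domains cover
#'   the grid.
#' @param grid Evaluation times.
#' @param sd_convention `"sample"` (divide by n-1, default) or
#'   `"population"` (divide by n).
#' @param deriv Derivative order summarized (default 0, the curves
#'   themselves).
#' @return Object of class `pointwise_summary`: `grid`, `mean`, `sd`,
#'   `min`, `max`, `n`, `sd_convention`, and `sd_degenerate` (`TRUE` when
#'   only one curve was supplied and the sd is reported as all-zero).
#' @export
pointwise_summary <- function(curves, grid, sd_convention = c("sample", "population"),
                              deriv = 0) {
  sd_convention <- match.arg(sd_convention)
  if (!length(curves)) stop("need at least one curve")
  Y <- vapply(curves, eval_curve, numeric(length(grid)), grid = grid, deriv = deriv)
  Y <- matrix(Y, nrow = length(grid))
  n <- ncol(Y)
  mu <- rowMeans(Y)
  degenerate <- FALSE
  if (n < 2) {
    warning("sd undefined for a single curve; reported as zero")
    s <- rep(0, length(grid))
    degenerate <- TRUE
  } else {
    ss <- rowSums((Y - mu)^2)
    s <- sqrt(ss / if (sd_convention == "sample") n - 1 else n)
  }
  structure(list(grid = grid, mean = mu, sd = s,
                 min = apply(Y, 1, min), max = apply(Y, 1, max),
                 n = n, sd_convention = sd_convention,
                 sd_degenerate = degenerate),
            class = "pointwise_summary")
}

#' @export
print.pointwise_summary <- function(x, ...) {
  cat(sprintf("<pointwise_summary> %d curves on %d grid points; mean range [%.3g, %.3g]\n",
              x$n, length(x$grid), min(x$mean), max(x$mean)))
  invisible(x)
}

#' Export a pointwise summary as a long-format data frame
#'
#' @param x A `pointwise_summary`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `time_days`, `statistic`, `value`.
#' @export
as.data.frame.pointwise_summary <- function(x, row.names = NULL, optional = FALSE, ...) {
  stats <- c("mean", "sd", "min", "max")
  do.call(rbind, lapply(stats, function(s)
    data.frame(time_days = x$grid, statistic = s, value = x[[s]],
               stringsAsFactors = FALSE)))
}
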