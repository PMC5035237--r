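# Functional regression of curves on treatment indicators: ordinary least
# squares solved independently at every grid point, giving per-treatment
# predicted curves and residual curves. With an indicator design and any
# replication, a group's predicted curve is the pointwise mean of that
# group's curves.

#' Build a treatment-indicator design
#'
#' Encodes group membership as an intercept plus reference-level
#' indicators (reference = first group alphabetically). Predictions are
#' coding-invariant; the coding only names the coefficient curves.
#'
#' @param groups Character vector, one treatment label per curve.
#' @return Object of class `f_design`: `groups` (factor), `X` (model
#'   matrix), `levels`.
#' @export
f_design <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  X <- stats::model.matrix(~g)
  colnames(X) <- c("(Intercept)", paste0("treatment", levels(g)[-1]))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "))
  }
  structure(list(groups = g, X = X, levels = levels(g)), class = "f_design")
}

curves_matrix <- function(curves, grid, deriv = 0) {
  Y <- vapply(curves, eval_curve, numeric(length(grid)), grid = grid, deriv = deriv)
  t(matrix(Y, nrow = length(grid)))   # n_curves x n_grid
}

#' Functional regression on treatment groups
#'
#' Fits, at every grid point, the ordinary least-squares regression of
#' curve values on the treatment design. Returns coefficient curves, one
#' predicted curve per treatment, residual curves, and the pointwise
#' residual sum of squares.
#'
#' @param curves List of curves (see [penalized_smooth()]).
#' @param design An [f_design()] with one group label per curve, or a
#'   character vector of labels.
#' @param grid Evaluation times.
#' @param deriv Derivative order analyzed (0 = the curves, 1 or 2 for
#'   derivative curves).
#' @return Object of class `fanova_fit`: `grid`, `coefficients`
#'   (design-column x grid matrix), `predicted` (treatment x grid matrix),
#'   `fitted` (curve x grid), `residuals` (curve x grid), `sse_curve`
#'   (pointwise residual SS), `design`, `deriv`.
#' @export
fit_fanova <- function(curves, design, grid, deriv = 0) {
  if (is.character(design) || is.factor(design)) design <- f_design(design)
  if (length(curves) != nrow(design$X))
    stop("number of curves does not match the design")
  if (any(table(design$groups) < 1)) stop("every group needs at least one curve")
  Y <- curves_matrix(curves, grid, deriv)
  qrX <- qr(design$X)
  cf <- qr.coef(qrX, Y)                        # p x n_grid
  fitted <- design$X %*% cf
  res <- Y - fitted
  # one predicted row per treatment: evaluate the fit at each level
  lev <- design$levels
  Xg <- stats::model.matrix(~factor(lev, levels = lev))
  pred <- Xg %*% cf
  rownames(pred) <- lev
  rownames(cf) <- colnames(design$X)
  structure(list(grid = grid, coefficients = cf, predicted = pred,
                 fitted = fitted, residuals = res,
                 sse_curve = colSums(res^2), design = design, deriv = deriv),
            class = "fanova_fit")
}

#' @rdname fit_fanova
#' @export
derivative_fanova <- function(curves, design, grid, deriv) {
  stopifnot(deriv %in% c(1, 2))
  fit_fanova(curves, design, grid, deriv = deriv)
}

#' @export
print.fanova_fit <- function(x, ...) {
  cat(sprintf("<fanova_fit> %d curves, %d groups, %d grid points%s\n",
              nrow(x$residuals), length(x$design$levels), length(x$grid),
              if (x$deriv > 0) paste0(" (derivative ", x$deriv, ")") else ""))
  invisible(x)
}

#' Export predicted treatment curves as a long-format data frame
#'
#' @param x An `fanova_fit`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `time_days`, `treatment`, `predicted`.
#' @export
as.data.frame.fanova_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(rownames(x$predicted), function(g)
    data.frame(time_days = x$grid, treatment = g, predicted = x$predicted[g, ],
               stringsAsFactors = FALSE)))
}
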