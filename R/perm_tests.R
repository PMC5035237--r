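# Permutation tests on curves. At every grid point a classical statistic
# (one-way F across treatments, or a two-sample t) is computed from the
# curve values; its null distribution is generated by permuting group
# labels across curves. Family-wise control over the whole time domain
# comes from the permutation distribution of the maximum statistic.

# one-way F at every grid point; Y is n_curves x n_grid, labels integer
pointwise_F <- function(Y, labels) {
  n <- nrow(Y)
  sizes <- tabulate(labels)
  k <- length(sizes)
  gm <- colMeans(Y)
  means <- rowsum(Y, labels) / sizes          # k x n_grid
  ssb <- colSums(sizes * (sweep(means, 2, gm))^2)
  ssw <- colSums((Y - means[labels, , drop = FALSE])^2)
  msw <- ssw / (n - k)
  degen <- msw <= 1e-12 * pmax(colMeans(Y^2), 1e-300)
  f <- ifelse(degen, 0, (ssb / (k - 1)) / msw)
  attr(f, "degenerate") <- degen
  f
}

# two-sample |t| (Welch form) at every grid point; labels in {1, 2}
pointwise_abs_t <- function(Y, labels) {
  A <- Y[labels == 1L, , drop = FALSE]
  B <- Y[labels == 2L, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums((A - rep(ma, each = na))^2) / (na - 1)
  vb <- colSums((B - rep(mb, each = nb))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degen <- se2 <= 1e-12 * pmax((colMeans(A^2) + colMeans(B^2)) / 2, 1e-300)
  t <- ifelse(degen, 0, abs(ma - mb) / sqrt(pmax(se2, 1e-300)))
  attr(t, "degenerate") <- degen
  t
}

# number of distinct relabelings, counted up to label swap for two
# equal-sized groups (the statistics are label-symmetric)
count_relabelings <- function(sizes) {
  n <- sum(sizes)
  cnt <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (length(sizes) == 2 && sizes[1] == sizes[2]) cnt <- cnt / 2
  round(cnt)
}

# enumerate all distinct label assignments (columns); for two equal-sized
# groups, position 1 is pinned to group 1 to halve the symmetric pairs
enumerate_relabelings <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  if (k == 2 && sizes[1] == sizes[2]) {
    picks <- utils::combn(n - 1, sizes[1] - 1)
    out <- matrix(2L, n, ncol(picks))
    out[1, ] <- 1L
    for (j in seq_len(ncol(picks))) out[picks[, j] + 1L, j] <- 1L
    return(out)
  }
  rec <- function(pos, sz) {
    if (length(sz) == 1) {
      m <- matrix(1L, length(pos), 1)
      rownames(m) <- pos
      return(m)
    }
    cols <- list()
    ch <- if (sz[1] == length(pos)) matrix(seq_along(pos), ncol = 1)
          else utils::combn(length(pos), sz[1])
    for (j in seq_len(ncol(ch))) {
      rest <- rec(pos[-ch[, j]], sz[-1])
      sub <- matrix(0L, length(pos), ncol(rest))
      rownames(sub) <- pos
      sub[as.character(pos[ch[, j]]), ] <- 1L
      sub[rownames(rest), ] <- rest + 1L
      cols[[j]] <- sub
    }
    do.call(cbind, cols)
  }
  out <- rec(seq_len(n), sizes)
  rownames(out) <- NULL
  out
}

perm_quantile <- function(x, alpha) {
  m <- length(x)
  sort(x)[min(m, ceiling((1 - alpha) * (m + 1)))]
}

# shared permutation engine
perm_engine <- function(Y, labels, stat_fun, grid, alpha, n_perm, seed) {
  if (n_perm < 19) stop("n_perm must be at least 19 to resolve alpha = 0.05")
  labels <- as.integer(labels)
  sizes <- tabulate(labels)
  if (any(sizes == 0)) stop("every group needs at least one curve")
  obs <- stat_fun(Y, labels)
  degen <- attr(obs, "degenerate")
  cnt <- count_relabelings(sizes)
  exhaustive <- cnt <= n_perm
  if (exhaustive) {
    L <- enumerate_relabelings(sizes)
    perm_stats <- apply(L, 2, function(l) as.numeric(stat_fun(Y, l)))
    n_used <- ncol(L)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_perm), function(i)
      as.numeric(stat_fun(Y, sample(labels))), numeric(length(grid)))
    n_used <- n_perm
  }
  perm_stats <- matrix(perm_stats, nrow = length(grid))
  perm_max <- apply(perm_stats, 2, max)
  max_obs <- max(obs)
  p <- if (exhaustive) {
    # the identity relabeling is in the enumeration, so p >= 1/n_used
    sum(perm_max >= max_obs - 1e-12) / n_used
  } else {
    (1 + sum(perm_max >= max_obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(
    grid = grid, statistic_curve = as.numeric(obs), max_observed = max_obs,
    pointwise_critical = apply(perm_stats, 1, perm_quantile, alpha = alpha),
    max_critical = perm_quantile(perm_max, alpha),
    p_value_max = p, alpha = alpha, n_perm = n_used, seed = seed,
    exhaustive = exhaustive, degenerate_points = as.logical(degen),
    perm_max = perm_max),
    class = "perm_test")
}

#' Permutation functional F-test across treatment groups
#'
#' Computes, at every grid point, the one-way ANOVA F of curve values
#' across groups (between-group mean square over within-group mean
#' square, from the same least-squares fit as [fit_fanova()]), and builds
#' its null by permuting group labels. When the number of distinct
#' relabelings does not exceed `n_perm`, the enumeration is exhaustive.
#' Grid points with zero within-group variance (identical replicates)
#' yield a statistic of 0 and are flagged in `degenerate_points`.
#'
#' @param curves List of curves.
#' @param design An [f_design()] or character vector of group labels.
#' @param grid Evaluation times.
#' @param alpha Envelope level; default 0.05.
#' @param n_perm Number of label permutations; default 1000.
#' @param seed Integer seed making sampled permutations reproducible.
#' @param deriv Derivative order tested (0 = the curves themselves).
#' @return Object of class `perm_test`: `statistic_curve`,
#'   `max_observed`, `pointwise_critical`, `max_critical`, `p_value_max`
#'   (the `+1` convention: never 0), `alpha`, `n_perm` (relabelings
#'   actually used), `seed`, `exhaustive`, `degenerate_points`.
#' @export
functional_F_test <- function(curves, design, grid, alpha = 0.05,
                              n_perm = 1000, seed = 1, deriv = 0) {
  if (is.character(design) || is.factor(design)) design <- f_design(design)
  if (length(curves) < 3) stop("need at least 3 curves in total")
  Y <- curves_matrix(curves, grid, deriv)
  perm_engine(Y, as.integer(design$groups), pointwise_F, grid, alpha, n_perm, seed)
}

#' Permutation functional t-test between two groups of curves
#'
#' Pointwise two-sample statistic
#' `|t|(t) = |mean_A - mean_B| / sqrt(s2_A/n_A + s2_B/n_B)` with a
#' label-permutation null; envelopes and p-value as in
#' [functional_F_test()].
#'
#' @param curves_A,curves_B Lists of curves, each of size >= 2.
#' @inheritParams functional_F_test
#' @return A `perm_test` object.
#' @export
functional_t_test <- function(curves_A, curves_B, grid, alpha = 0.05,
                              n_perm = 1000, seed = 1, deriv = 0) {
  if (length(curves_A) < 2 || length(curves_B) < 2)
    stop("each group needs at least 2 curves (pointwise variance undefined otherwise)")
  Y <- curves_matrix(c(curves_A, curves_B), grid, deriv)
  labels <- rep(1:2, c(length(curves_A), length(curves_B)))
  perm_engine(Y, labels, pointwise_abs_t, grid, alpha, n_perm, seed)
}

#' Permutation F-test on curve derivatives
#'
#' Delegates to [functional_F_test()] applied to the derivative-evaluated
#' curves; with `deriv = 0` it is identical to the plain test.
#'
#' @inheritParams functional_F_test
#' @export
test_on_derivatives <- function(curves, design, grid, deriv, alpha = 0.05,
                                n_perm = 1000, seed = 1) {
  functional_F_test(curves, design, grid, alpha = alpha, n_perm = n_perm,
                    seed = seed, deriv = deriv)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> max statistic %.4g vs critical %.4g (alpha = %g); p_max = %.4g\n",
              x$max_observed, x$max_critical, x$alpha, x$p_value_max))
  cat(sprintf("  %d %s relabelings, seed %d%s\n", x$n_perm,
              if (x$exhaustive) "exhaustive" else "sampled", x$seed,
              if (any(x$degenerate_points)) sprintf(", %d degenerate grid points",
                                                    sum(x$degenerate_points)) else ""))
  invisible(x)
}

#' Export a permutation test as a data frame
#'
#' @param x A `perm_test`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `time_days`, `statistic`,
#'   `pointwise_critical`.
#' @export
as.data.frame.perm_test <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_days = x$grid, statistic = x$statistic_curve,
             pointwise_critical = x$pointwise_critical)
}
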