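# Published monitoring tables, typed in independently of the packaged
# CSVs: the oracle for fixture checksums and hand-arithmetic checks.
# 5 treatments x 2 replicates at days 1..380; NA = unquantified count.

fix_times <- c(1, 15, 38, 52, 80, 137, 250, 380)
fix_treatments <- c("CC", "CI", "CII", "CT", "RT")

# columns: CC.1 CC.2 CI.1 CI.2 CII.1 CII.2 CT.1 CT.2 RT.1 RT.2
tab_yeast <- matrix(c(
  3.45, 5.48, 1.78,   NA, 1.60,   NA, 3.03, 3.03, 3.20, 3.20,
  5.06, 5.11, 3.62, 5.26, 5.19, 5.55, 5.87, 5.58, 5.84, 4.08,
  4.95, 4.94, 4.70, 4.97, 5.13, 4.66, 5.02, 4.99, 5.42, 5.15,
  4.73, 5.13, 5.00, 5.12, 4.99, 5.18, 3.30, 3.90, 4.34, 5.18,
  4.36, 5.24, 4.68, 4.46, 4.01, 4.35, 4.06, 3.20, 3.95, 4.48,
  5.58, 5.41, 5.70, 5.73, 4.90, 5.30, 6.02, 5.48, 5.15, 4.20,
  4.79, 5.85, 5.06, 4.81, 4.90, 4.75, 5.39, 4.45, 4.70, 4.92,
  3.82, 3.74, 2.20, 1.78, 4.62, 2.93, 5.10, 4.25, 3.78, 4.62),
  nrow = 8, byrow = TRUE)

tab_ph <- matrix(c(
  2.71, 2.71, 2.37, 2.37, 2.40, 2.40, 2.71, 2.71, 2.71, 2.71,
  3.79, 3.73, 3.32, 3.32, 3.33, 3.35, 4.32, 4.39, 4.42, 4.48,
  4.21, 4.17, 3.91, 3.79, 3.96, 3.99, 4.34, 4.40, 4.35, 4.45,
  4.26, 4.21, 3.97, 3.95, 4.17, 4.06, 4.36, 4.43, 4.35, 4.33,
  4.46, 4.30, 4.13, 3.91, 4.12, 4.08, 4.34, 4.44, 4.40, 4.36,
  4.41, 4.15, 4.22, 4.13, 4.21, 4.17, 4.38, 4.35, 4.32, 4.31,
  4.62, 4.25, 4.28, 4.08, 4.28, 4.23, 4.30, 4.30, 4.31, 4.36,
  4.43, 4.00, 4.08, 4.01, 4.14, 4.09, 4.55, 4.21, 4.20, 4.24),
  nrow = 8, byrow = TRUE)

tab_acidity <- matrix(c(
  0.61, 0.61, 2.40, 2.40, 1.60, 1.60, 0.61, 0.61, 0.61, 0.61,
  0.49, 0.49, 1.59, 1.87, 1.26, 1.33, 0.49, 0.49, 0.44, 0.44,
  0.37, 0.38, 1.53, 1.50, 1.20, 1.18, 0.40, 0.40, 0.40, 0.31,
  0.43, 0.43, 1.55, 1.48, 1.12, 1.14, 0.43, 0.43, 0.41, 0.41,
  0.49, 0.47, 1.51, 1.37, 1.06, 1.12, 0.39, 0.41, 0.39, 0.34,
  0.77, 0.81, 1.91, 1.92, 1.68, 1.59, 0.54, 0.53, 0.54, 0.54,
  0.44, 0.71, 1.75, 2.02, 1.47, 1.55, 0.46, 0.50, 0.44, 0.38,
  0.94, 1.11, 2.36, 2.45, 1.89, 2.01, 0.43, 0.59, 0.53, 0.48),
  nrow = 8, byrow = TRUE)

tab_col <- function(tab, treatment, replicate) {
  j <- (match(treatment, fix_treatments) - 1) * 2 + replicate
  tab[, j]
}

# series directly from the typed tables (bypasses the packaged CSVs)
oracle_series <- function(tab, treatment, replicate, variable) {
  v <- tab_col(tab, treatment, replicate)
  ferm_series(treatment, replicate, variable, fix_times, v)
}

# independent trapezoid (used as the hand oracle against the package's)
oracle_trap <- function(t, y) {
  ok <- !is.na(y)
  t <- t[ok]; y <- y[ok]
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}
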