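---
title: "Functional analysis of fermentation curves: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional analysis of fermentation curves: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermcurve)
```

## The problem

Table-olive fermentations run for a year or more and are sampled on a
handful of days — here days 1, 15, 38, 52, 80, 137, 250 and 380 — with
two replicate vessels per treatment. Classical day-by-day ANOVA wastes
this structure: it multiplies tests across sampling days and says
nothing about the trajectory between them. The functional view treats
each replicate's time course (yeast counts in log10 cfu/ml, pH,
titratable acidity in g lactic acid/100 ml) as one observation — a
smooth curve — and compares *curves* across the five brining/
acidification treatments (CC, CI, CII, CT, RT) bundled with the
package.

## Smoothing model

Each series is represented as a B-spline expansion
$f(t)=\sum_k c_k B_k(t)$ whose coefficients minimize the penalized
criterion

$$\sum_j \big(y_j - f(t_j)\big)^2 \;+\; \lambda \int f''(t)^2\,dt .$$

Choices, and why:

* **Basis**: order 4 (cubic pieces) with interior knots at the interior
  observation times — for the bundled eight-day schedule that is six
  knots, ten basis functions. Cubic order is the minimum that leaves
  the *second* derivative meaningful, and downstream comparisons use
  first and second derivatives (acidification rate and its change).
  Knots at observation times are standard practice for sparse
  irregular sampling; an equally-spaced rule is also provided.
* **Penalty**: integrated squared second derivative, computed exactly
  by per-span Gauss–Legendre quadrature (the integrand is piecewise
  polynomial, so a fixed small number of nodes per knot span is exact,
  not approximate).
* **λ selection**: generalized cross-validation,
  $\mathrm{GCV}(\lambda)=n\,\mathrm{RSS}/(n-\mathrm{df}_\lambda)^2$,
  minimized over 33 log-spaced candidates in $[10^{-2},10^{6}]$. One λ
  is chosen *per variable* (the summed GCV score across that
  variable's series), so all curves entering a between-treatment
  comparison carry the same amount of smoothing. On the bundled data
  GCV sits at the small end of the grid: with eight points and ten
  basis functions GCV is known to undersmooth, and the resulting
  curves are near-interpolating. That is acceptable for the tests —
  which compare groups of curves smoothed identically — but users
  wanting visually smoother trajectories can fix λ directly.
* **Missing observations** (the unquantified day-1 yeast counts in two
  replicates) are dropped from the least-squares fit; the basis and
  domain are unchanged, so the curve remains defined on all of
  [1, 380]. The reader (`nd_policy`) can instead substitute a
  detection-limit value; the default keeps them missing because the
  data source does not define the entries.
* **Degenerate systems**: with λ = 0 and more basis functions than
  points the normal equations are singular; the fit refuses with an
  instruction rather than silently regularizing.

Evaluation, differentiation and integration of the fitted curves are
linear in the coefficients; integration is again exact per-span
quadrature. Curves serialize to JSON with doubles carried as `%.17g`
strings so a round trip is bit-exact.

## Functional descriptive statistics and regression

`pointwise_summary()` computes mean, SD (sample convention by default;
population available), min and max across curves at each grid point.
`fit_fanova()` solves, at every grid point, the ordinary least-squares
regression of curve values on an intercept-plus-treatment-indicator
design (reference level = first treatment alphabetically; predictions
are coding-invariant). With indicator designs the predicted curve of a
treatment equals the pointwise mean of its curves, and
fitted + residual reconstructs each curve exactly — both are tested
invariants. The regression runs on the evaluation grid rather than in
coefficient space so curves with different bases can be mixed; for a
shared basis the two formulations coincide.

## Permutation tests on curves

At each grid point the one-way F statistic
$F(t)=\frac{\mathrm{SSB}(t)/(k-1)}{\mathrm{SSW}(t)/(n-k)}$ (or the
two-sample statistic
$|t|(t)=|\bar y_A-\bar y_B|/\sqrt{s_A^2/n_A+s_B^2/n_B}$) is computed
from the curve values. The null distribution comes from permuting
treatment labels across curves:

* **Exhaustive enumeration** replaces random sampling whenever the
  number of distinct relabelings is at most `n_perm`; for two
  equal-sized groups relabelings are counted up to the label swap
  (the statistics are label-symmetric), so four curves in two pairs
  yield exactly three distinct splits.
* **Envelopes**: the pointwise critical curve is the per-grid-point
  $(1-\alpha)$ null quantile; the maximum critical value is the same
  quantile of the null maxima, which controls the family-wise error
  over the whole domain. Quantiles use the order statistic of rank
  $\lceil(1-\alpha)(m+1)\rceil$, which makes the rejection rule exact
  for sampled permutations.
* **p-values** follow the +1 convention,
  $p=(1+\#\{\max F^{(\pi)}\ge \max F\})/(n_\mathrm{perm}+1)$, so they
  are never zero; exhaustive runs include the identity relabeling in
  the null set.
* **Degenerate grid points** — zero within-group variance, which the
  bundled data produce at day 1 where replicate pH values are printed
  identical — would give infinite statistics; they are set to 0 and
  flagged (`degenerate_points`) instead, on the view that a time point
  with no within-group variability carries no usable evidence for this
  statistic.
* **Determinism**: sampled permutations are driven by an explicit seed
  and the caller's RNG state is restored afterwards; identical inputs
  and seed give bit-identical results.

Calibration is verified by simulation: under a two-treatment
exchangeable null (identical asymptotic-exponential means, Gaussian
noise SD 0.2, six replicates per arm so that label sampling — not
exhaustive enumeration — is exercised, 199 permutations) the
family-wise rejection rate over 200 seeded replicates stays within two
Monte-Carlo standard errors of the nominal 0.05. Six replicates are
used rather than the study's two because four curves admit only three
distinct relabelings — a permutation test cannot resolve α = 0.05
there, which is itself a documented property, not a defect.

## Area-under-curve ANOVA and Fisher LSD

Each replicate series is summarized by the trapezoid area below its
non-missing observations; treatments are compared by one-way ANOVA on
these areas and all pairwise Fisher LSD tests
($\mathrm{LSD}=t_{1-\alpha/2,\,\mathrm{df_w}}\sqrt{\mathrm{MS_w}(1/n_i+1/n_j)}$,
difference reported larger-mean-first). The raw trapezoid is the
default because it reproduces the published pH and acidity treatment
means of the bundled dataset exactly after rounding; a
smoothed-integral alternative is provided because the published
*yeast* areas are consistent only with areas taken under smoothed
curves (whose exact configuration is not recoverable — the package's
smoothed means agree to within a few percent for four of five
treatments, the exception being the treatment with an unanchored
missing day-1 count). Group SEs default to the sample convention
(sd/√n); the population convention is exposed and reproduces the
published SE column for the two-replicate design, where it equals
|difference|/(2√2).

## Kinetics

Acidification is modelled as the asymptotic exponential
$y = a + b(1-e^{-cx})$: start value $a$, overall change $b$, rate $c$
(days⁻¹), asymptote $a+b$. Replicates are pooled (not averaged) per
treatment, matching the 16-point fits whose standard errors the
bundled data reproduce. Fitting uses Levenberg–Marquardt with
deterministic starts $a_0=\min y$, $b_0=\mathrm{range}(y)$,
$c_0=0.05$, tolerance $10^{-10}$, 500 iterations; SEs are the
asymptotic $\sqrt{\widehat\sigma^2\,[(J^\top J)^{-1}]_{kk}}$. Fits
that stall return `converged = FALSE` with the optimizer's message
rather than an error or a fabricated estimate: on the bundled data the
CT treatment converges with rate SE exceeding the estimate (its pH
jumps to its plateau between the first two sampling days, so the rate
is essentially unidentified at this sampling resolution) and RT fails
outright — both faithfully reported as diagnostics.

## Synthetic data generator

`synthetic_spec()`/`generate_dataset()` emulate the study's data
shapes with known ground truth: the asymptotic exponential for
pH-like monotone saturation, a C¹ rise–plateau–decline arc
(`yeast_arc`: quadratic rise hitting the peak exactly at `peak_time`,
then a smooth decline approaching slope `-decline_rate`) for
microbial curves, and arbitrary tabulated shapes. Defaults mirror the
study conditions: the eight-day sampling schedule, two replicates,
i.i.d. Gaussian observation noise (nothing in the data motivates
heavier tails, and the permutation machinery needs only
exchangeability), and an optional drop-first-k missing policy
emulating unquantified early plate counts. Generation is
seed-deterministic.

What the generator does *not* emulate: coupling between microbial and
chemical variables, replicate-level random effects (noise is
independent across time points within a replicate), and
heteroscedasticity. Passing calibration tests therefore demonstrate
correctness of the statistical machinery under exchangeable Gaussian
noise, not robustness to correlated or heavy-tailed measurement error
in real fermentations.

## Problem sizes used in the test suite

The suite exercises the bundled dataset in full (30 series × 8 points,
daily evaluation grids of 380 points where the contract demands it,
coarser grids of 25–80 points where only cross-method agreement is
checked). Simulation-based properties use 200 null replicates with 199
permutations for test calibration and 100 seeded replicates for
kinetic parameter recovery — sizes at which Monte-Carlo error is small
relative to the tolerances asserted, while the whole suite runs in
well under a minute.

## Known limitations

* No monotone or positivity-constrained smoothing: pH curves can
  undershoot at the boundary where data are sparse.
* The functional regression supports categorical (treatment)
  covariates only.
* Fisher LSD is the only post-hoc procedure implemented.
* GCV with very sparse series (8 points) tends to undersmooth; fixing
  λ by eye remains a legitimate and sometimes preferable choice for
  presentation graphics.
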