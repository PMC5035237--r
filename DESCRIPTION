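Package: fermcurve
Title: Functional Data Analysis of Fermentation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyzes sparse replicated fermentation monitoring data as
    smooth curves: penalized B-spline smoothing with generalized
    cross-validation, pointwise functional descriptive statistics,
    functional regression across treatments, permutation functional F-
    and t-tests with family-wise critical envelopes, area-under-curve
    ANOVA with Fisher LSD pairwise comparisons, and nonlinear
    asymptotic-exponential kinetic fits. Includes a complete 380-day
    table-olive fermentation monitoring dataset (yeast counts, pH,
    titratable acidity) and a seeded synthetic-data generator for test
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
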