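Package: hqgamm
Title: Hierarchical Generalized Additive Models for Isokinetic Torque-Angle
    Curves and Functional Hamstring-to-Quadriceps Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling joint-angle-specific isokinetic knee
    torque-angle curves with two-level Bayesian generalized additive models:
    a common population P-spline smoother plus per-athlete random intercepts
    and random smooth-shape deviations, fitted by a conjugate blocked Gibbs
    sampler. Includes preprocessing of long-format dynamometer exports
    (truly-isokinetic velocity filtering, best-repetition selection),
    posterior-predictive torque-angle curves with credible bands,
    joint-angle-specific functional hamstring-to-quadriceps ratio curves with
    point-of-equality crossings and extrema, WAIC model comparison, and a
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    splines,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
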