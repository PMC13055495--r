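Package: multistress
Title: Classify Interactions Between Paired Ecological Stressors in Factorial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fully factorial two-stressor experiments
    (e.g. warming crossed with nutrient pollution) from survey time series
    and factorial RNA-seq count matrices. Simulates repeated-measures
    factorial survey data and negative-binomial gene counts with known
    ground truth, fits per-date generalised linear models (including
    Firth bias-reduced logistic and Beta regression), season-wide
    generalised additive mixed models with plate random intercepts, and
    per-gene negative-binomial factorial models. The fitted interaction
    coefficient is interpreted against a multiplicative null model on the
    link scale and classified into synergism, antagonism, or reversal,
    with an equivalence band around the null (smallest effect size of
    interest) used to flag mild deviations. Includes per-gene interaction
    typing with Benjamini-Hochberg adjustment, tidy outputs, ggplot2
    visualisations, and a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2 (>= 1.40.0),
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
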