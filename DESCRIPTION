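Package: raymix
Title: Ray-Design Mixture Toxicity Analysis for Binary Chemical Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for concentration-response analysis of binary chemical
    mixtures assayed by fixed-ratio ("ray") designs, as used in algal
    growth-inhibition toxicology. Builds geometric dilution series and
    direct equipartition ray (EquRay) mixture designs, converts plate-style
    optical-density readings to growth-inhibition effects, fits two-parameter
    Logit and Weibull concentration-response curves by multi-start nonlinear
    least squares, derives ECx, NOEC/LOEC and delta-method confidence bands,
    predicts mixture toxicity under Concentration Addition (Loewe additivity)
    and Independent Action (Bliss independence), and classifies each mixture
    ray as additive, synergistic or antagonistic against observation-based
    confidence intervals. A seeded plate-data simulator with CA, IA and
    dose-modifier truths makes the whole pipeline testable without raw data.
License: MIT
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
    minpack.lm,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
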