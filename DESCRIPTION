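Package: beltddm
Title: Drift-Diffusion and Psychometric Analysis of Split-Belt Speed Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing human perception of belt-speed
    differences during split-belt treadmill walking with two-alternative
    forced-choice (2AFC) data. Provides closed-form drift-diffusion model
    (DDM) quantities and a seeded Euler-Maruyama trial simulator, a
    balanced stimulus-schedule generator for the mirrored/flipped block
    design, a synthetic-cohort generator with response-window censoring,
    trial preprocessing (accuracy coding, exclusion rules), logistic
    psychometric fitting (per-subject maximum likelihood and hierarchical
    random-effects models) with point-of-subjective-equality (PSE),
    just-noticeable-difference (JND) and Weber-fraction estimates,
    chronometric DDM fitting to mean reaction times that predicts choice
    behavior from reaction times alone, and cohort-level reporting with
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
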