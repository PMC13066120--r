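Package: metasense
Title: Metacognitive Sensitivity and Efficiency Analysis for Confidence Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring metacognition from trial-level confidence
    judgements: Type-2 receiver operating characteristic curves and their
    area (AUROC), mutual-information measures of metacognitive sensitivity
    (meta-J) and efficiency (meta-J2r) with maximum-information binarization,
    normalized stimulus discriminability and folded X-pattern tables,
    two-level confidence-accuracy association tests (Pearson correlations,
    Fisher r-to-z two-sample comparison, regression slope-difference tests),
    and mixed-design factorial ANOVA with Greenhouse-Geisser correction,
    generalized eta squared, and Bonferroni-corrected pairwise comparisons.
    Includes a signal-detection-flavoured synthetic cohort generator for
    agent groups with graded (human-like) or compressed (LLM-like)
    confidence, and a pipeline that runs the full analysis behind one
    configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
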