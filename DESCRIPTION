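Package: durpsych
Title: Simulation and Analysis of Two-Interval Duration-Comparison Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing two-interval forced-choice
    duration-comparison experiments run with the method of constant stimuli.
    Generates synthetic observer populations whose latent points of subjective
    equality (PSE) can be linked to a trait score (the Autism Spectrum
    Quotient) and shifted by pharmacological treatment arms; simulates
    trial-level binary choices through a Boltzmann (logistic) psychometric
    function; fits per-observer psychometric curves by maximum likelihood or
    least squares to recover PSE and difference limen; and provides the
    inferential layer used in this literature (t tests with Cohen's d,
    mixed-design ANOVA with partial eta squared and Cohen's f, Pearson
    correlation, median splits, and bivariate bootstrap resampling of group
    means), together with end-to-end experiment replication templates and a
    CSV/JSON command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
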