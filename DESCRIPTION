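Package: optoca1
Title: In-Silico Optogenetic Excitability of CA1 Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the optogenetic excitability of hippocampal CA1-like
    neurons expressing ChR2(H134R). Couples a double two-state photocurrent
    model to multicompartment conductance-based neurons illuminated by a
    Monte Carlo simulated optical-fiber light field, and provides the
    analysis layer around it: stimulation-threshold titration by bisection,
    total temporal averaged current (TAC), the surface of fiber positions
    for the activation of neurons (SoFPAN) with discretization bounds,
    strength-duration (Lapicque) and log-linear threshold regression,
    Wilcoxon signed-rank excitability scoring, and Morris elementary-effects
    sensitivity screening with a radial Sobol design. A synthetic-morphology
    generator produces CA1-like pyramidal cells and interneurons so the full
    pipeline runs without external data; SWC import is supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
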