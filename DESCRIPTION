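Package: polarsim
Title: Reaction-Diffusion Modeling of Apical-Basal Polarity in Renal Epithelial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the emergence and disruption of apical-basal polarity in a
    one-dimensional renal epithelial cell as a twelve-field reaction-diffusion
    system coupling integrin activation, the Rho-GTPases Cdc42, Rac and Rho, and
    the mutually inhibitory Par and Scribble polarity complexes. Provides an
    explicit finite-difference solver with no-flux boundaries, polarization
    metrics based on apical-basal concentration differences, a multiparametric
    sensitivity analysis combining Latin hypercube sampling with
    Kolmogorov-Smirnov distances and dummy-parameter significance thresholds,
    in-silico integrin-dose and GTPase degradation/upregulation experiments, and
    a utility converting western-blot band intensities to intracellular molar
    concentrations. Results are returned as tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
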