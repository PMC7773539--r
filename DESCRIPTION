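Package: bibswarm
Title: Self-Propelled Particle Swarms with Bayesian and Inverse Bayesian
    Inference and Levy-Walk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates Vicsek-type self-propelled particle (SPP) swarms in
    which each agent's deviation from local velocity matching is decided by
    Bayesian inference (BO model) or by coupled Bayesian and inverse
    Bayesian inference (BIB model), and provides the analysis stack for the
    resulting trajectories: step-length extraction by bending-angle
    segmentation, tornado/splash/translation behavior indexes with
    nonparametric model comparisons, and Levy-walk detection by maximum
    likelihood fitting of a hard-truncated power law against an exponential
    with Kolmogorov-Smirnov selection of the lower cutoff and Akaike-weight
    model selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
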