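Package: dopadist
Title: Distributional Coding Analysis of Projection-Defined Dopamine Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dopamine-neuron encoding during
    Pavlovian trace conditioning. Generates synthetic sessions (task events,
    population-specific spike trains, two-channel fiber photometry) with known
    ground truth; quantifies single-unit encoding with peri-stimulus time
    histograms and Poisson generalized linear models; measures tonic firing
    regularity (CV2) and bursts/pauses by robust Gaussian surprise; clusters
    population responses on principal components; processes photometry to dF/F
    with reference-channel motion correction; and fits a distributional
    temporal-difference model with asymmetric learning rates whose converged
    state values are reward-distribution expectiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ape,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
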