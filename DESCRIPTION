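Package: olfeedback
Title: Cortical Feedback and Gated Readout Models of Olfactory Pattern
    Convergence and Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of how unstructured cortical feedback to the olfactory
    bulb, combined with high-threshold gating of bulbar projections to
    piriform cortex, reshapes the similarity of cortical odor
    representations.  Provides an exact analytic statistical model of
    module responses and threshold-gated cortical activation (the linear
    law for the change in cosine similarity as a function of initial
    similarity), a finite-population Monte-Carlo simulator that serves as
    a brute-force oracle and generalizes the analysis to Gaussian
    responses and sigmoid transfer, a geometric generator of mitral
    cell-granule cell dendrodendritic connectivity, an Izhikevich
    conductance-based spiking network of the bulb, and a reduced
    firing-rate-distribution model with a random threshold-gated cortical
    readout for large-scale in silico odor-pair experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Matrix,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
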