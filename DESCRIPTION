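Package: fatiguenet
Title: Correlation Network Analysis of Exercise-Induced Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses weighted correlation networks of mechanical
    and physiological variables measured during exhaustive exercise at several
    effort intensities. Provides a calibrated synthetic cohort generator,
    hyperbolic critical-power model fitting (Tlim = AWC/(P - CP)), Pearson
    correlation thresholding into weighted symmetric connection matrices,
    node influence metrics (degree, eigenvector influence, betweenness
    centrality, discrete influence-state dynamics), one-way ANOVA with
    Student-Newman-Keuls post hoc comparisons across intensities, and an
    end-to-end reproducible pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
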