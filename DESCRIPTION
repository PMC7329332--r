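Package: statefc
Title: State-Dependent Cortical Functional Connectivity and Slow-Wave Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline relating cortical brain states to resting-state
    functional connectivity. Generates synthetic cohorts of BOLD-like ROI time
    series (modular persistent activity versus slow-wave activity driven by
    population down-up transitions) and fiber-photometry calcium traces with
    known ground truth; detects slow calcium waves with an exponential-moving-
    average procedure; computes partial-correlation connectivity with nuisance
    covariables and per-matrix FDR cutoffs, fALFF spectral statistics, and
    distance-dependence regressions; derives weighted brain-graph metrics
    (modularity, efficiency, clustering, path length); quantifies matrix
    similarity via eigenvalue spectra for dynamic connectivity; and links
    down-up transition counts to connectivity with permutation and
    repeated-measures correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
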