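Package: wplinbs
Title: EEG Source-Network Analysis with WPLI, Network-Based Statistics
    and Consensus Modularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-limited functional connectivity analysis for region-level
    electrophysiological time series. Estimates weighted phase lag index (WPLI)
    matrices from windowed Fourier cross-spectra, locates group-differential
    subnetworks with covariate-adjusted Network-Based Statistics (permutation
    family-wise error control on connected-component intensity), characterises
    network segregation through weighted modularity with agreement-matrix
    consensus partitions, and relates functional findings to streamline-count
    structural connectivity (tract comparisons and structure-function rank
    correlations). Ships a two-group synthetic cohort generator with a planted
    differential-coupling subnetwork so the full pipeline is testable end to
    end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
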