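Package: depthscan
Title: Detection of Under- and Over-Covered Genomic Regions from Per-Base
    Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic regions of interest (ROIs) that are
    significantly under- or over-covered in high-throughput sequencing
    data, from per-base coverage tracks in the three-column BED dialect
    produced by 'bedtools genomecov -d'. The coverage series is detrended
    by an efficient running median (with support for circular
    chromosomes), the normalized coverage is modelled with a
    two-component Gaussian mixture fitted by expectation maximization,
    and per-base z-scores drive a double-threshold (hysteresis)
    clustering of events. Each reported region carries robust statistics
    (mean and max z-score, mean coverage, copy-number ratio). A coverage
    simulator with Poisson or read-placement noise, low-frequency trends
    and injected copy-number events supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
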