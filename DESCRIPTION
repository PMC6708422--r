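Package: polysweep
Title: Simulation-Calibrated Selection Scans for Selfing Polyploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of diploid and
    allopolyploid populations with partial selfing, recombination and
    recurrent mutation, used to generate neutral null distributions that
    calibrate significance thresholds for four selection statistics:
    sliding-window Fst, the integrated haplotype score (iHS), the number of
    segregating sites by length (nSL) and the cross-population composite
    likelihood ratio (XPCLR). Includes the demographic scenario of the
    Australian hexaploid wheat breeding population (taxon founding, two
    polyploidization events, Fst-tracked cohort differentiation, SNP-array
    ascertainment emulation, outcrossing-rate calibration against an LD-decay
    target), sweep-region calling and merging, Hill-Robertson r2 linkage
    disequilibrium tools with an inter-region LD criterion and cluster
    analysis, and packaged fixtures of the published sweep-region and
    inter-region r2 tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    igraph,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
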