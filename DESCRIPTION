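Package: occycle
Title: Nucleosome Occupancy Dynamics over the Yeast Respiratory Oscillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved DNA-occupancy measurements in
    metabolically synchronous yeast continuous cultures. Normalizes dual-channel
    MNase tiling-array time series by the least-variant-set/LOESS procedure,
    subtracts micrococcal-nuclease digestion bias to obtain log2 DNA occupancy,
    aligns heterogeneous datasets onto a common respiratory phase-angle axis
    derived from dissolved oxygen, builds spline-smoothed average-cycle
    profiles, computes TSS- and dyad-aligned median occupancy maps and
    cluster-wise expression dynamics, provides Fourier oscillation statistics
    and DFT band-pass filtering, and relates chromatin dynamics to cellular
    energetics through adenylate energy charge and a competitive
    product-inhibition model of chromatin-remodeler activity. Includes a fully
    seeded synthetic-data generator that emulates the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
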