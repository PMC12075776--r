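Package: sparsegrowth
Title: Instantaneous Growth Rates from Sparse Microbial Growth Curves,
    with Capsule Morphometrics and Recruitment Ecology Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates instantaneous doubling rates from sparse, irregularly
    sampled microbial growth curves by sliding-window log2 regression with
    candidate-rate pooling and median aggregation, and delimits the
    exponential phase by fitting a decreasing sigmoid to the rate-versus-time
    series. Summarizes growth across condition grids (temperature, salinity,
    carbon) into growth envelopes. Also provides capsule (spherocylinder)
    cell morphometrics from segmented projected areas and multi-point radius
    measurements, deterministic medium-design calculators (chlorinity to
    salinity, two-batch mixing series, molar-ratio carbon mixes), ecology
    summaries for metagenomic read recruitment (RPKM normalization,
    subcluster abundance sums, ANI-threshold species clustering, genome
    quality scores, abundance-environment correlation), and seeded synthetic
    data generators so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
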