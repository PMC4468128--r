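Package: cimld
Title: Composite Interval Mapping for Lattice-Design Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: QTL mapping for recombinant inbred line (RIL) populations
    phenotyped in simple lattice (incomplete block) field designs.
    Implements composite interval mapping directly on plot-level
    observations (CIMLD): the block-within-replication covariance is
    estimated by lattice ANOVA and removed by generalized-least-squares
    whitening before each QTL test, so no information is lost to mean
    summaries.  Also provides the two conventional strategies it is
    compared against -- composite interval mapping on arithmetic line
    means (RCBD) and on lattice-adjusted line means (AMLD) -- together
    with a multiple-imputation pseudo-marker scan, permutation-based
    genome-wide LOD thresholds, QTL calling with 1.5-LOD support
    intervals, a multi-environment (QTL-by-environment) scan, and a
    simulation framework for power and false-discovery-rate studies
    under varying block variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
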