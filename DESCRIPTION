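Package: HiCcontrasts
Title: Comparative Analysis of Hi-C Contact-Map Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing chromosome architecture between Hi-C samples:
    iterative-correction (ICE) balancing and coverage-matched downsampling of
    binned contact matrices, interaction-frequency decay curves with log-log
    slope fitting and Kuiper CDF statistics, non-parametric selection and
    clustering of top-scoring interactions, a copy-number and length aware
    null model for trans-contact propensity, the Local Score Differentiator
    (LSD) domain-boundary caller built on the directionality index with local
    Tukey fences, boundary-class comparison between samples, Crane-style
    insulation scores, point-feature and insulator enrichment around boundary
    classes, aggregate pairwise contact pile-ups, and 4C fragment enrichment
    tracks. A synthetic contact-map generator with known ground truth
    (distance-decay exponent, TAD boundaries and insulation strengths,
    copy-number scaling, trans fraction) supports parameter-recovery testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
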