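Package: mosaicmorph
Title: Morphometry of Genotyped Neurons in Mosaic Brains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative morphometry of single-neuron SWC
    reconstructions and mosaic cell-size data from X-inactivation
    mosaic brains.  Implements Sholl analysis with exact sphere-crossing
    segment partitioning, centrifugal branch-order statistics (branch
    counts, lengths, partition asymmetry, contraction), soma and nucleus
    area measurement from traced outlines, per-animal X-chromosome
    inactivation ratios, and the group-statistics layer used to compare
    neuronal genotypes (mixed repeated-measures ANOVA with Bonferroni
    post-tests, rank tests, regression slope comparison, and
    size-distribution fitting).  A calibrated synthetic-data generator
    produces SWC arbor populations and mosaic cell-size cohorts so the
    whole pipeline can be exercised and validated without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
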