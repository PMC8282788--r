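Package: thiolspan
Title: Gene-Set Overlap Statistics and Lifespan-Curve Analysis for
    Dietary-Thiol Aging Studies in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis toolkit for dietary-thiol aging studies
    in Caenorhabditis elegans. Provides the representation-factor gene-set
    overlap statistic over a fixed gene universe (expected overlap, exact
    hypergeometric tail probability computed by log-gamma summation, and its
    normal approximation), construction of analysis gene sets from
    differential-expression tables by fold-change and rank thresholds,
    Boltzmann-sigmoid survival-curve fitting with per-experiment
    percent-change statistics and paired t-tests, bench-assay statistics
    (stress-survival fractions, DTNB/glutathione linear calibration with
    protein normalization, box-plot style group summaries), synthetic-data
    generators with planted truth for every pipeline stage, and a
    configuration-driven pipeline with TSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
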