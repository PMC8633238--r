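Package: mrdseq
Title: Tumor-Informed Methylation and Mutation Analysis of Molecular
    Residual Disease in Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the circulating-tumor-DNA fraction ("MD ratio") of a
    plasma cell-free DNA sample from tumor-specific methylation blocks by
    binomial-mixture maximum likelihood, scores molecular residual disease
    (MRD) with a Wald statistic, and calls positivity at the standard-normal
    1.96 cutoff. Includes patient-specific methylation-block selection
    against a healthy-donor plasma panel, plasma somatic-mutation tracking
    (maximum allelic fraction, tissue-plasma concordance, ctDNA clearance),
    longitudinal cohort summaries (per-timepoint detection rates, exact
    2x2 comparisons, rank correlations, recurrence lead times), and a
    seeded synthetic-cohort generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
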