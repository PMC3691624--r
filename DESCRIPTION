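Package: rareCGH
Title: Multi-Sample Rank-Based Detection of Rare Copy-Number Variants
    from aCGH Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects rare (<= 1% cohort frequency) copy-number variants from
    array comparative genomic hybridization (aCGH) logratio cohorts. Each
    probe column is transformed to pseudo-ranks, which removes genome-wide
    wave artifacts and experimenter bias; a sliding-window mean Manhattan
    distance statistic flags (sample, window) pairs in the upper 1% tail of
    a window-wise Beta null as rare-CNV markers; a cohort polymorphic
    profile built from the segmentation removes markers in polymorphic
    regions; surviving markers score pre-existing segments by coverage
    density, and candidate segments are annotated against pathogenic and
    benign interval databases. Includes a synthetic cohort generator with
    planted ground truth for end-to-end evaluation, and a minimal recursive
    binary segmenter for plumbing when no external segmentation is
    supplied.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
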