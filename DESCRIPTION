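Package: chromkinetics
Title: Kinetic Analysis of Histone-Mark and Accessibility Time Courses
    After Acute Protein Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for degron (PROTAC) time-course
    epigenomics. Provides minimum-coverage and ERCC spike-in normalization,
    a self-contained negative-binomial Wald test for per-site differential
    signal with Benjamini-Hochberg correction, promoter and CpG-island
    window annotation of changed sites, kinetic classification of promoters
    by the speed of H3K4me3 loss (fast/slow and intensity tertiles),
    cross-mark trajectory and overlap summaries, putative-enhancer
    definition by triple mark intersection, ATAC fragment-size nucleosome
    partitioning, TSS metaprofiles, and a synthetic-data generator that
    encodes the assumed exponential-decay kinetics with ground-truth labels
    so every stage is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
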