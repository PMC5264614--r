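Package: msapqtl
Title: CCGG Methylation Typing, Epigenetic QTL Mapping and Marker
    Segregation Analysis for Outbred F1 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for methylation-sensitive dual restriction-enzyme
    (HpaII/MspI) genotyping of CCGG sites and downstream population
    epigenetics in outbred F1 (CP) mapping populations. Calls per-sample
    hemi- and full-methylation states from cleavage/body read evidence,
    classifies population-level methylation (polymorphic/monomorphic,
    hemi/full by majority rule) and parent-to-F1 inheritance classes,
    computes gene-body methylation metaprofiles and windowed region
    methylation levels, detects differentially methylated regions and
    intersects them with differential-expression calls, derives cold
    tolerance and yield phenotype indices from plant-level scores, and
    performs methylation-phenotype association scans (Pearson t-test),
    Mendelian segregation filtering of dominant markers, two-point
    linkage statistics and single-marker Kruskal-Wallis QTL scans. A
    synthetic-data generator simulates parents, F1 progeny, read-level
    evidence, markers and phenotypes with planted effects so that every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
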