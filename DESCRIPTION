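Package: wgsdx
Title: Diagnostic Variant Prioritisation and Yield Statistics for Clinical Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Genome", "Diagnostics", email = "genomedx@example.org", role = c("aut", "cre"))
Description: A tiered prioritisation pipeline for clinical whole-genome
    sequencing in paediatric genetics. Filters and ranks small variants
    (SNVs and indels) under explicit mode-of-inheritance models including
    compound-heterozygote candidates, parses and classifies read-depth
    copy-number variants and junction-based structural variants, measures
    concordance between microarray and sequencing CNV calls by reciprocal
    overlap and breakpoint distance, screens for medically actionable
    secondary findings against the 56-gene ACMG panel, and computes cohort
    diagnostic-yield statistics (two-proportion chi-squared tests, Wilson
    confidence intervals, subgroup and multi-locus yields). Ships a
    deterministic synthetic-cohort generator with a ground-truth manifest
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
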