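Package: somafilt
Title: Configurable Two-Stage Filtering of Somatic Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of somatic SNV calls from matched tumor/normal
    sequencing. Stage one traverses the tumor and normal BAM files and computes
    a per-sample panel of read-level metrics (depth, allele counts, variant
    allele frequency, base/mapping quality medians, strand counts, position-in-
    read statistics, soft-clip and edit-distance summaries) for every candidate
    variant, with chunked caching for resumability. Stage two applies a fully
    configurable set of named threshold filters (default and ICGC-style
    presets, or a user-supplied tab-delimited configuration) and emits a
    standard filtered VCF annotated in the FILTER column, per-variant results,
    summary counts and plots. Includes a truth-set evaluator (recall,
    precision, F1) and a seeded synthetic fixture generator that plants true
    somatic variants and one artifact class per filter, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    ggplot2,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
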