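Package: varlocus
Title: A Genome-Centered Engine for Locus-Specific Variant Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory, genome-centered engine for curated variant
    databases with case-level data. Variants are stored per observation in a
    two-table layout (genomic and per-transcript records) with
    observation-independent DBID grouping, gene- and disease-scoped custom
    columns, and role-based record visibility. Includes a pragmatic HGVS
    parser with genomic/cDNA coordinate mapping and single-codon consequence
    prediction, a whole-exon reading-frame checker, bulk import/export
    (tab-delimited section files, VCF in, BED out) with one-change update
    semantics, retrieval/submission/federated query surfaces, a dual-transcript
    effect-conflict analysis with an exact two-sided Fisher test, and a
    deterministic synthetic fixture generator for offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
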