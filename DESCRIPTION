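Package: pkdpanel
Title: Targeted NGS Variant Prioritization and Read-Depth CNV Detection for
    ADPKD Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic analysis for targeted next-generation sequencing of the
    autosomal dominant polycystic kidney disease genes PKD1 and PKD2, whose
    duplicated 5' region is mirrored in six pseudogenes at ~97.7% sequence
    identity. Implements the variant prioritization cascade (both-strand
    support, >=20% allele fraction, <5% population frequency with
    pathogenic-database rescue), molecular consequence annotation on a
    transcript model, Variant Score (VS) based pathogenicity classification,
    CoNIFER-style SVD-ZRPKM read-depth calling of large deletions, per-base
    coverage auditing with low-coverage reporting, and cohort-level diagnostic
    rate summaries. Ships the published validation and discovery cohort tables
    as fixtures and a synthetic-data generator (gene plus diverged pseudogene
    copies, pseudogene-leakage variant calls, Poisson coverage matrices with
    spiked deletions) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
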