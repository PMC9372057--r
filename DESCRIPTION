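Package: genotoxscreen
Title: Genotoxicity Screening of Nuclease-Edited Cell Populations from
    Deep Panel, Exome and Genome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for deciding whether any variant
    called in CRISPR-edited cell populations is attributable to nuclease
    activity. Given per-sample variant calls from edited and mock-treated
    arms (multiple donors, timepoints and technical replicates), the
    package applies a replicate-concordance step, a synonymous-effect
    filter, a germline-database occurrence filter, mock-arm subtraction
    and an optional strict nuclease filter (indels with guide-RNA homology
    only), each stage logged in an auditable ledger. It also provides a
    depth-to-limit-of-detection model calibrated at a panel operating
    point, a simplified tumor-normal somatic comparison with a
    label-inversion control, sliding-window spacer+PAM homology scoring,
    coding-effect annotation against compact gene models, and a fully
    deterministic synthetic-cohort generator (reference, genes, guides,
    germline database, per-sample VCFs and a planted-variant truth table)
    so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
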