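Package: triodnv
Title: De Novo Variant Detection and Quality Control for Sequenced Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects de novo variants (DNVs) in parent-child trios from a pair
    of joint-genotyped multi-sample VCFs produced by two independent variant
    callers. Implements allele normalization and multi-allelic decomposition,
    exact cross-caller callset intersection, an eight-rule DNV filter with a
    per-rule audit trail, classification of exome DNVs into high- and
    low-confidence capture zones with an mpileup-based rescue test,
    confirmation of DNVs against independent high-coverage pileup evidence,
    and callset quality metrics (per-individual counts, CpG fraction,
    transition/transversion ratio, n-way callset overlap). A synthetic trio
    simulator generates Mendelian-consistent fixtures with planted DNVs and
    per-rule filter violations so the full workflow is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
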