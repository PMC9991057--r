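Package: m1ascope
Title: m1A Epitranscriptome Analysis from MeRIP-Seq Coverage Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and downstream analysis of N1-methyladenosine (m1A)
    sites from MeRIP-seq pileup data. Implements four complementary site
    detection methods (Poisson window enrichment peaks, A-to-T
    reverse-transcription misincorporation, coverage-trough RT truncation,
    and rescue of normal peak shape after chemical m1A-to-m6A conversion)
    with a two-or-more-method consensus rule; transcript-region annotation
    and metagene profiles; differential methylation and expression with
    negative-binomial tests; ceRNA and lncRNA-RBP network assembly with
    miRNA seed scanning; non-negative matrix factorization pattern discovery
    with cophenetic rank selection; and permutation-based transcription
    factor activity scoring. Ships a seeded synthetic-data generator that
    plants m1A sites carrying all three biochemical signatures so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
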