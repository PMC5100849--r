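Package: poolmapeval
Title: Simulation-Based Evaluation of Read Mapping for Pool-Seq Polymorphism Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing how read-mapping choices distort allele
    frequency estimates from pooled sequencing (Pool-Seq). Provides a
    truth-bearing paired-end read simulator built on a two-template design
    (a reference chassis and a variant chassis carrying SNPs at fixed
    spacing and short indels between them), an oracle aligner with a
    controllable mismapping model, alignment quality filters, mpileup-style
    allele counting with PoPoolation2 sync input/output, per-site
    differentiation statistics (FST, Fisher exact test, Cochran-Mantel-
    Haenszel test), truth-based evaluation metrics (true/false positive
    SNPs, extreme allele-frequency outliers), quality-filter comparisons
    (mapping quality, allele count, base quality, strand bias, external
    site lists), and the two-mapper intersection strategy that suppresses
    mapper-specific artifact peaks in genome-wide scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
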