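Package: duplexmask
Title: Weak/Strong Base-Pair Mask Analysis of Peptide-dsDNA Binding
    Specificity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the double-stranded DNA binding
    specificity of short peptides from docking-style affinity scores.
    Enumerates the unique duplex space of DNA k-mers under
    reverse-complement equivalence, clusters per-sequence affinity scores
    by weak/strong (W/S) base-pair masks into summary tables, computes
    the mask coincidence probability, and scans gene promoter sequences
    for best-binding sequences and degenerate masks across the four
    strand/orientation variants. Ships a calibrated synthetic score
    model and a planted-motif promoter generator so the whole pipeline
    runs with known ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
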