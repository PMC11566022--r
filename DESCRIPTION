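Package: pisliceR
Title: Pachytene piRNA Cleavage-Target Calling from Degradome and Small RNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for deciding which transcripts are cleaved by
    pachytene piRNAs. Implements absolute small-RNA quantification with UMI
    deduplication and spike-in calibration, 5'-monophosphorylated RNA
    (degradome) cleavage-product detection, abundance-tiered guide:target
    pairing rules anchored at the Argonaute slicing register, high-confidence
    target calling with locus-exclusivity and genotype-dependence filters,
    replicate-permutation summaries, negative-binomial differential abundance,
    translational-efficiency and RNA polymerase II density contrasts, and a
    synthetic-data generator with planted ground truth so the entire pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
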