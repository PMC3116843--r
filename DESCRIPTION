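Package: mirmeth
Title: Screening for DNA-Methylation-Regulated microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide identification of microRNAs
    silenced by DNA methylation in cancer cell lines. Calls significantly
    methylated regions from MBD-enrichment sequencing read counts under a
    Poisson background model, screens miRNA stem-loop annotations for
    proximal methylation in a methylated reference line versus a
    demethylated derivative, tests expression concordance (Welch's t test
    with Benjamini-Hochberg correction and a fold-change gate), quantifies
    re-expression after demethylating-drug treatment by the 2^-ddCt method
    with cross-cell-line confirmation, scores bisulfite clone sequences
    per CpG, classifies genomic context and host-gene transcriptional
    independence, and emits a per-stage candidate funnel report. A
    synthetic-data module generates a two-cell-line world with planted
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
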