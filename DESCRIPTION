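Package: endocargo
Title: Organelle-IP Proteomics Analysis of Endocytic Cargo
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for organelle immunoprecipitation (Endo-IP /
    Lyso-IP) quantitative proteomics. Provides a synthetic-data generator
    with planted ground truth, moderated empirical-Bayes differential
    enrichment of tagged versus untagged IPs with Benjamini-Hochberg FDR,
    compartment and set-overlap summaries, hypergeometric gene-set
    enrichment, k-means clustering of differentiation time-course profiles,
    candidate endocytic-cargo classification from transmembrane and cell
    membrane annotations, SNX27 PDZ and SNX17 FERM sorting-motif scanning,
    peptide-window extraction, ipTM-threshold screening with control sets,
    and position-frequency-matrix sequence logos.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    cluster,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
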