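Package: xenocrosstalk
Title: Cross-Species Ligand-Receptor Crosstalk Analysis for Xenograft
    Transcriptomes with Preclinical Response Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers tumor-to-stroma paracrine signals from dual-species
    (human tumor / mouse stroma) xenograft expression data. Implements
    probe significance prefiltering, cross-hybridizing probe removal,
    largest-mean probe-to-gene collapse, per-contrast differential
    expression with Benjamini-Hochberg adjustment, intersection of
    tumor-expressed ligands with stroma-expressed receptors through a
    directional ligand-receptor compendium, and detection of ligands
    regulated only under combination therapy. Also provides a preclinical
    response layer (caliper tumor volumes, CR/DR/SR/NR response
    classification, Kaplan-Meier and log-rank support, delta-delta-Ct
    quantification) and seeded synthetic-data generators with planted
    ground truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    IRanges,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Microarray, Software
RoxygenNote: 7.3.3
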