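Package: fibroTalk
Title: Spatially Resolved Fibroblast-CD4 T Cell Crosstalk Analysis for
    Allergic Nasal Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies stromal-immune crosstalk in single-cell resolution
    spatial transcriptomics of nasal mucosa. Provides cell- and sample-level
    quality control, library-size log-normalization, radius (20 micron)
    neighbor graphs, permutation-based neighborhood enrichment with
    Benjamini-Hochberg correction, gene-module signature scoring with binned
    control genes, per-cell fibroblast pro-Th2 ligand scores and sample-level
    crosstalk scores, Wilcoxon differential expression, hypergeometric
    pathway enrichment, a self-contained ligand-receptor permutation test,
    and clinical correlation. Includes a synthetic spatial-tissue generator
    that plants cell-type composition, immune-stromal adjacency, ligand
    upregulation, Th2 coupling and clinical severity coupling at
    configurable effect sizes, for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
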