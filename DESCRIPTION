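Package: netrepurpose
Title: Network Propagation and Transcriptional Reversal Screening for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies drug repurposing candidates for complex diseases by
    propagating disease seed genes over a protein-protein interactome with a
    heat-kernel diffusion model, selecting a disease network from the top
    diffusion ranks, intersecting it with approved drug-gene interactions,
    and ranking drugs by how strongly their induced expression perturbations
    anti-correlate (Spearman) with genetically imputed disease-associated
    expression. Includes a summary-statistics transcriptome-wide imputation
    stage (the S-PrediXcan statistic), readers for GCT v1.3 signature
    matrices and DGIdb-style interaction tables, and a fully ground-truthed
    synthetic data generator for validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
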