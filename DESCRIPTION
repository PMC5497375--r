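Package: pivotnet
Title: Pivot Gene Detection in Co-Expression Networks on a Protein
    Interaction Scaffold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds co-expression networks by overlaying Pearson
    correlation of stage-wise expression profiles on a protein-protein
    interaction scaffold, clusters them with a native implementation of
    the Markov cluster algorithm (MCL), selects GO-enriched functional
    gene modules, and detects inter-modular hubs and pivot genes by
    one-sided hypergeometric tests.  Also provides the surrounding
    analysis machinery: TPM normalisation and expressed-gene filtering,
    Illumina-style probe collapsing and quantile normalisation,
    two-sample differential expression with fold-change and
    Benjamini-Hochberg FDR rules, multi-condition gene-set overlap
    (Venn) arithmetic, qPCR ddCt relative quantification, chi-square
    proportion tests for centrosome-abnormality counts, and a
    synthetic-data generator with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
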