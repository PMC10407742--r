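Package: dmsbench
Title: Pairwise Benchmarking of Variant Effect Predictors with Deep
    Mutational Scanning and Clinical Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks variant effect predictors (VEPs) against deep mutational
    scanning (DMS) functional scores by pairwise shared-variant Spearman
    tournaments, and ranks predictors and DMS score sets against
    pathogenic/putatively-benign clinical variant labels by pairwise
    AUROC/AUBPRC tournaments, with bootstrap outranking significance.
    Includes single-nucleotide-reachability filtering with most-benign
    imputation, scanning-window exclusion of poorly predicted regions,
    representative-assay selection, and a synthetic benchmark generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
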