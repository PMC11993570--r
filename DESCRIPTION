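Package: radsig
Title: Radiogenomic Association of MRI Radiomic and Immune Gene Expression
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for radiogenomic association analysis in head and neck
    squamous cell carcinoma: reconstruction of published MRI radiomic
    prognostic signatures (linear feature combinations) and immune-related
    gene expression signatures (EntrezID-weighted sums) from tabular inputs,
    Spearman correlation of radiomic scores with gene signature scores and
    immune cell fractions, filtering of gene signatures by a consensus
    k-means / silhouette cluster-stability procedure, and evaluation of
    radiomic classifiers of dichotomized gene signature status via repeated
    stratified holdout with SMOTE rebalancing and support vector machines.
    Includes a latent-factor synthetic cohort generator with planted ground
    truth so the full pipeline is testable without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    knitr,
    mclust,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
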