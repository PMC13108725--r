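Package: macpolar
Title: Screening Tumor Cell Lines for Macrophage-Polarization Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks tumor cell lines by their capacity to polarize primary
    macrophages, from multiplexed secreted-analyte measurements of
    tumor-conditioned-media experiments. Implements robust modified z-score
    phenotype scoring with lower-limit-of-quantification handling, donor
    variance decomposition via random-intercept linear mixed models
    (intraclass correlation with likelihood-ratio tests, Tukey-Kramer
    post-hoc contrasts, Nakagawa R-squared), Spearman rank-correlation
    screens of gene expression against polarization scores with
    Benjamini-Hochberg and Storey q-value control, quartile-based
    negative-binomial Wald differential expression with empirical-Bayes
    fold-change shrinkage, pre-ranked gene set enrichment analysis with
    permutation-based normalized enrichment scores, and permutation tests
    for cell-line and tumor-type overrepresentation in score quartiles.
    A synthetic-data module generates donor-structured secretome and
    linked RNA-seq experiments with known ground truth so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    fgsea,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
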