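Package: doublehit
Title: Integrative Blood DNA-Methylation and GWAS Candidate-Gene Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for nominating "double-hit" candidate genes in
    frontotemporal dementia (FTD) and FTD with amyotrophic lateral sclerosis
    (FTD-ALS) by combining blood 450K DNA-methylation profiles with GWAS
    summary statistics. Implements the preprocessing cascade for beta-value
    matrices (empirical-Bayes batch adjustment, probe filtering, K-nearest
    neighbour imputation, zero-mean normalisation), per-probe differential
    methylation with Benjamini-Hochberg control, unsupervised class discovery
    (hierarchical clustering with Davies-Bouldin model selection, PCA),
    hypergeometric enrichment against tissue-specificity and pathway gene
    sets, the double-hit overlap and candidate filter over annotated GWAS
    summary statistics, Spearman co-expression network prioritisation by gene
    degree, and an expression-based validation meta-analysis with moderated
    t-statistics. A synthetic-data module generates every input the pipeline
    consumes so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
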