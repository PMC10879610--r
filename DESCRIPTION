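Package: microcooc
Title: Gut Microbiota Co-Occurrence, Genetic Distance, and Environmental Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links pairwise co-occurrence of gut-microbiota amplicon sequence
    variants (ASVs) to their genetic distance, community diversity, and
    housing covariates. Computes a co-occurrence index (Spearman rank
    correlation of relative abundances within treatment groups) from ASV
    count tables, pairwise p/JC69 distances from aligned 16S sequences,
    alpha-diversity summaries, bootstrap-validated co-occurrence networks
    with hub detection, and Gaussian GLMs with exhaustive AIC model
    selection and subsample robustness checks. Includes a Gaussian-copula
    synthetic-data generator with known ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
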