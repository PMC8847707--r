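Package: nicheoptima
Title: Niche-Optimum Modelling of Microbial Activity Along Environmental
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Culture-independent niche modelling for microbial community
    data. Fits hierarchical logistic (Huisman-Olff-Fresco) response models
    to per-taxon relative abundances of 16S rRNA transcripts along
    rescaled environmental gradients, selects the response shape by
    small-sample corrected AIC with bootstrap stabilisation, and extracts
    niche optima and inner niche widths. Downstream analytics cover
    ecological distances and Spearman correlation networks with
    multi-level modularity community detection, PCA ordination,
    phylogenetic signal of niche optima (Blomberg's K and phylogenetic
    signal-representation curves from phylogenetic eigenvector
    regression), divergence-versus-relatedness regressions for terminal
    clade pairs, and Procrustes concordance between niche and phenotype
    ordinations. A synthetic-data module generates gradients, read
    counts, ultrametric trees, tip traits and trait matrices with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    multcomp,
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
    mclust,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
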