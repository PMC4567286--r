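Package: micropair
Title: Paired-Host Microbiome Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community analysis for paired-host 16S amplicon
    surveys: reading and validating classic tab-separated OTU tables,
    sample metadata and rooted phylogenies; alpha diversity (observed
    richness, Chao1, Faith's phylogenetic diversity, Good's coverage,
    rarefaction curves); rarefied beta diversity (Hellinger, unweighted
    and weighted UniFrac); per-OTU aggregation via the corrected moment
    estimate of the negative-binomial parameter k; and two permutation
    tests of within-breeding-pair community similarity (a sample-centred
    test on mean within-pair distance and an OTU-centred test on the mean
    Fisher-z-transformed within-pair Spearman correlation, with
    standardised effect sizes). A synthetic paired-community generator
    with tunable within-pair correlation, zero inflation and colony
    structure exercises the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phyloseq,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
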