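Package: ipwclust
Title: Inverse-Probability Weighted Clustering for Gene-Based
    Rare-Variant Association Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association screening for genes carrying multiple,
    potentially rare variants. Genotypes of the SNPs in a gene are collapsed
    into a partition of individuals: pairwise similarity is scored with an
    inverse-probability weighting that overweights shared minor alleles,
    converted to a bounded distance, and clustered with Ward's method.
    Association between the partition and quantitative or dichotomous traits
    is then tested with one-way ANOVA, the chi-square test of independence,
    and the partition-retention I statistic, with Bonferroni or top-fraction
    selection across genes and selection counting over phenotype replicates.
    Includes a mini-exome simulator (rare-variant-heavy minor allele
    frequency spectrum, fixed genotypes, replicated phenotypes with known
    causal effects) so the whole screen can be exercised and calibrated
    without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
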