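Package: svclust
Title: Structural-Variant Merging Under Breakpoint Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges multi-sample structural-variant (SV) call sets affected by
    breakpoint uncertainty. Implements two dissimilarity measures between SV
    intervals (relative overlap and maximum breakpoint distance), three
    clustering strategies over the resulting threshold graph (trivial,
    corrected, and trio-constrained clustering with cannot-link constraints
    derived from merging-incompatible genotype pairs), dataset-quality metrics
    (Mendelian-error fraction, Mendelian-consistent merges of error clusters,
    kinship-category separation with the proportion-of-shared-alleles
    estimator, and the fraction of variants in Hardy-Weinberg equilibrium),
    a within-type row-shuffling null model, and a synthetic pedigree cohort
    generator with controlled breakpoint-jitter and decomposed-variant errors
    for end-to-end validation.
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
    igraph,
    purrr,
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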