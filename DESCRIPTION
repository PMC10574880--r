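Package: coretheme
Title: Thematic Core Collections for Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trait-directed ("thematic") core collections from crop
    germplasm banks. Genotypic values are predicted per accession with
    EM-REML/BLUP under an unbalanced multi-environment mixed model, accessions
    are ranked and truncated per theme, near-duplicates are pruned with
    identity-by-state (IBS) kinship, and the resulting collections are
    validated against the entire collection with Shannon-Weaver phenotypic
    diversity, Nei gene-diversity statistics (Ho, Hs, Fis), allele retention,
    Cohen's Kappa coincidence, PCA and discriminant analysis of principal
    components (DAPC). A synthetic-germplasm generator with known ground truth
    supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
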