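Package: polyasite
Title: Minimal-Feature Polyadenylation Site Modelling Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a four-feature polyadenylation (poly(A))
    site classifier from cleavage-site-anchored DNA sequences: upstream and
    downstream trimer position score matrices (PSM), a cleavage-site dimer
    PSM, and a nucleosome-occupancy matrix (NOM) score, combined by logistic
    regression or linear discriminant analysis. Includes PCA-based
    localization of cis-elements from position-by-kmer matrices, a
    second-order Markov generator of false (negative) site sequences,
    stratified repeated cross-validation with sensitivity, specificity and
    Matthews correlation coefficient, cross-species model transfer with
    reciprocal sensitivity, sliding-window genome scanning, and a synthetic
    data generator emulating poly(A) site anatomy for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
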