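Package: corrlink
Title: Recombination Fraction Estimation via Pearson Correlation, Linkage
    Maps and Genomic Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pairwise recombination fractions in selfing F_t
    biparental populations from the Pearson correlation of allele-count
    genotype codes (theta = (1 - r)/2), alongside two EM reference
    estimators (codominant three-genotype model and the classical
    dominant four-phenotype model) with Louis observed-information
    standard errors. Provides segregation-distortion chi-square
    diagnostics, Haldane linkage-map construction from adjacent-marker
    estimates, a mechanistic F_t population simulator (gamete-level
    meiosis with Poisson crossovers, single-seed descent, optional
    segregation distortion), and a genomic-mating workflow: REML
    variance components for additive plus dominance kinships, GBLUP
    breeding values, marker-effect back-solving, progeny prediction by
    Mendelian expectation and by simulated meiosis, and exhaustive
    mate-allocation search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
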