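Package: tetrablup
Title: Pedigree Mixed Models for Autotetraploid Breeding Programs with
    Double Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of autotetraploid (e.g. potato)
    breeding programs from pedigree and multi-trial phenotype records.
    Builds the tetraploid numerator relationship matrix as a function of
    the double-reduction rate, fits uni- and bivariate mixed models with
    additive, line, genotype-by-trial-by-year and specific-combining-
    ability random effects by average-information REML, estimates the
    double-reduction rate by profiling the restricted likelihood over a
    grid of rates, computes plot-level narrow- and broad-sense
    heritabilities and likelihood-ratio model comparisons, and validates
    predictions with five-fold and leave-one-breeding-cycle-out
    cross-validation. Includes a breeding-program simulator with
    tetraploid gene dropping that doubles as a Monte-Carlo
    identity-by-descent oracle for the relationship matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
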