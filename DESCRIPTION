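Package: dmiscan
Title: Segregation Distortion and Epistatic Incompatibility Scans for
    Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting Dobzhansky-Muller incompatibilities from
    genotype ratios in experimental hybrid crosses. Implements single-locus
    goodness-of-fit tests against Mendelian expectations, relative-viability
    estimates with delta-method standard errors, between-group heterogeneity
    tests, and hierarchical two- and three-locus nonindependence statistics
    that absorb lower-order distortion (observed-marginal expectations and
    iterative proportional fitting), together with inter-chromosomal test
    enumeration and Bonferroni bookkeeping. Includes a forward simulator of
    F2 intercrosses, backcrosses and second-generation backcross intercrosses
    with sex-limited (achiasmatic) recombination and configurable single-locus
    and epistatic viability selection, modelled on crosses between divergent
    populations of the copepod Tigriopus californicus.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
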