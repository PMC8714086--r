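Package: pedlion
Title: Pedigree-Based Genetic Diversity Analysis for Captive Studbook Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genetic diversity of small captive
    populations from studbook pedigrees. Implements pedigree validation and
    canonical ordering, the four standard pedigree-completeness measures
    (maximum, complete and equivalent generations, and the MacCluer
    completeness index), Wright's numerator relationship matrix via the
    tabular method, inbreeding and average-relatedness coefficients,
    individual increases in inbreeding and co-ancestry with the matching
    effective population size estimators, probability-of-gene-origin
    parameters (effective numbers of founders and ancestors, founder genome
    equivalents by co-ancestry and by gene dropping) with the associated
    partition of genetic diversity loss, generation intervals along the four
    parent-offspring pathways, subpopulation differentiation (pedigree FST,
    UPGMA dendrograms, relationship-matrix PCA), average-relatedness-based
    mating group classification with minimum-kinship pair recommendation,
    and a synthetic studbook simulator with known ground truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
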