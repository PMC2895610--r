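Package: idpopgen
Title: Population-Genetic and Ecological Statistics for Intermediate
    Species Divergence in Cyclic Parthenogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and dating intermediate genetic divergence
    between closely related, cyclically parthenogenetic zooplankton species
    sampled across many lake populations. Implements labelled-alignment data
    handling with the diploid two-allele-copy convention, median-joining
    haplotype networks with inferred median vectors, the genealogical sorting
    index with permutation tests and balanced subsampling, mismatch
    distributions with the sudden-expansion model (SSD goodness of fit,
    parametric-bootstrap confidence intervals, expansion dating), Tajima's D
    and the four-gamete test, hierarchical analysis of molecular variance
    (AMOVA) with stratified permutation significance, a moment-based
    isolation-model divergence-time estimator, and the predation-rate
    coefficient for laboratory predation trials. A coalescent simulator
    (single population, sudden expansion, and two-population
    isolation-with-migration with stepwise growth) generates data with the
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
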