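Package: mrtwin
Title: Family-Based Mendelian Randomization via Digital-Twin Conditional Randomization Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for a causal effect of an exposure trait on an outcome trait
    using genetic instruments and family genotype data. The core test compares
    a genetically-predicted-outcome statistic computed on true offspring against
    the same statistic on "digital twins" -- synthetic offspring genotypes
    resampled from parental (or duo/sibling) genotypes under Mendelian
    inheritance -- yielding a conditional randomization test that is immune to
    confounding from population stratification, assortative mating, and
    dynastic effects. Includes summary-statistic MR estimators (ratio,
    inverse-variance weighted, Egger), marginal GWAS and instrument selection
    with Bonferroni and F-statistic filters, a Balding-Nichols two-population
    simulator with configurable stratification confounding, and benchmark
    drivers for false-positive-rate and power experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
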