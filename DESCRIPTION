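Package: twinpaf
Title: Population Attributable Fractions from Monozygotic Twin Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the contribution of genetics plus shared exposures to
    chronic-disease risk from monozygotic (MZ) twin pair counts. Given the
    numbers of concordant and discordant MZ pairs in a cohort, the package
    computes probandwise concordance, the relative risk implied by the
    individual-level two-by-two co-twin exposure table, and the case-based
    population attributable fraction P*(RR-1)/RR, with percentile bootstrap
    intervals. It bundles a compiled 28-disease Western European MZ twin
    dataset, reproduces its summary statistics under explicit quantile
    conventions, links attributable fractions to mortality tables to estimate
    attributable deaths, and ships a liability-threshold twin-cohort simulator
    for estimator-consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pracma
Config/testthat/edition: 3
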