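Package: pesrisk
Title: Outcome Modeling for Polygenic Embryo Screening Under the
    Liability Threshold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the reduction in complex-disease risk achievable by
    polygenic embryo screening for a single disease under the liability
    threshold model.  Provides deterministic (numerical-integration) and
    Monte-Carlo estimates of relative and absolute risk reduction for two
    selection strategies (high-risk exclusion and lowest-risk
    prioritization), conditional analyses given parental polygenic scores
    or disease status, per-couple risk-reduction distributions, the risk
    increase of a genetically negatively correlated disease, risk
    reductions for dichotomized quantitative traits, and a genome-level
    Mendelian embryo simulator (map-based Poisson recombination, additive
    polygenic scoring, ascertainment-corrected logistic risk) for
    empirical validation on synthetic phased cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
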