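Package: nestnorm
Title: Thermal Reaction Norms and Nesting-Activity Indices for Sea Turtle
    Beaches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how sand colour shapes olive ridley sea
    turtle (Lepidochelys olivacea) nesting ecology on the Pacific coast of
    Central America. Implements sand-darkness scoring from image pixel
    blocks with per-image light/dark standardization, a spatio-temporal
    nesting-index model (year totals under constant, exponential or
    year-specific dynamics, time-constant beach proportions, Gaussian
    likelihood with count-proportional dispersion, AIC selection with
    Akaike weights, imputation of unobserved beach-year cells), thermal
    reaction norms for sex ratio (logistic, pivotal temperature and
    transitional range of temperatures) and hatching success
    (double-logistic) fitted by binomial maximum likelihood with
    Metropolis-Hastings credible intervals, Mantel permutation tests and
    albedo regressions, and a synthetic-data generator that emulates the
    nesting-count and constant-temperature incubation databases so the
    full pipeline is testable without the original data sources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    geosphere,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
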