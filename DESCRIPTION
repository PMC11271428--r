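Package: metstab
Title: Stability, Adaptability and Genetic Parameters for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of balanced multi-environment variety trials laid out as
    randomized complete blocks within environments. Provides individual and
    joint analysis of variance with selective accuracy, expected-mean-square
    variance components and genetic parameters (heritability, coefficients of
    variation, expected genetic advance), Scott-Knott clustering of genotype
    means, AMMI and GGE singular-value decompositions with biplot coordinates,
    which-won-where mega-environment partitioning, a battery of parametric and
    nonparametric stability indices (ecovalence, Lin-Binns superiority,
    Annicchiarico confidence indices, Eberhart-Russell and Perkins-Jinks joint
    regression, Nassar-Huehn rank statistics, AMMI stability value), BLUP-based
    simultaneous selection statistics (harmonic mean of genotypic values and
    the weighted average of absolute interaction scores), and Spearman
    rank-concordance analysis of the stability methods. A configurable
    synthetic trial generator with the variance structure assumed by the
    analysis is included, together with a worked cassava variety-trial summary
    dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
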