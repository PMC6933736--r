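Package: gardenQG
Title: Quantitative Genetics of Clonal Common-Garden Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-year clonal common-garden experiments
    in forest trees. Implements REML estimation of random-intercept linear
    mixed models with type-III tests, Satterthwaite denominator degrees of
    freedom, likelihood-ratio tests for random effects, least-squares means
    and BLUPs; genotype- and population-level phenotypic plasticity between
    measurement years; Bayesian nested variance components with Qst credible
    intervals and Weir-Cockerham Fst with bootstrap intervals for divergence
    testing; Lande-Arnold phenotypic selection differentials and gradients
    with permutation significance and stabilizing/disruptive classification;
    and correlated trait-climate evolution under bivariate Brownian motion on
    a genotype phylogeny, with stepping-stone marginal likelihoods and log
    Bayes factors. A synthetic-data generator with known ground truth
    (variance layers, latitudinal clines, fitness surfaces, Balding-Nichols
    markers, Brownian tip data) supports parameter-recovery testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    withr
Config/testthat/edition: 3
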