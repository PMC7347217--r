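Package: twinherit
Title: Twin-Study Heritability Estimation by Classical, Fingerprinting and
    Machine-Learning Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for classical twin designs.
    Simulates twin cohorts with known additive genetic (A), common
    environment (C), dominance (D) and unique environment (E) variance
    fractions, cross-measure genetic correlation and retest occasions; then
    estimates heritability by Falconer twin correlations with ACE/ADE model
    selection and reliability disattenuation, re-identifies individuals and
    monozygotic co-twins by Euclidean-distance behavioral fingerprinting
    with a permutation null, decomposes phenotypic correlations into
    genetic and environmental components via a cross-twin cross-trait
    moment estimator, derives qualitative heritability profiles from the
    feature weights of univariate, ridge and random-forest classifiers of
    monozygotic versus dizygotic pair differences, extracts latent factors
    by principal axis factoring with Promax rotation, and tests domain
    differences with Monte Carlo permutation tests. Every stage is
    validated by parameter recovery on the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ranger,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
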