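Package: cytodyn
Title: Diurnal Inflammatory Mediator Dynamics After Blunt Trauma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-of-injury effects on systemic
    inflammation after severe blunt trauma. Classifies injuries into day and
    night windows, propensity-matches the two cohorts on age, sex and injury
    severity, compares circulating mediator trajectories with two-way ANOVA
    (Mann-Whitney and Spearman auxiliaries), infers windowed correlation
    networks over adjacent 8-hour periods with a network-density statistic
    (Dynamic Network Analysis), and learns dynamic Bayesian network structure
    over time-sliced mediator panels by exact enumeration of bounded parent
    sets under a linear-Gaussian score. A seeded synthetic-cohort generator
    emulates the study design (32 mediators, serial sampling over 7 days,
    group-by-time effects, block-correlated log-normal noise) for testing and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
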