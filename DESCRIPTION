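Package: invasim
Title: Digital Host-Pathogen Coevolution and Time-Travelling Invasion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced digital host-pathogen coevolution world (a desk-scale
    stand-in for Avida-style artificial-life systems) together with the paired
    "time-travelling invasion" experimental protocol and its outcome analytics.
    Free-living digital hosts evolve on a toroidal grid, rewarded for performing
    nine logic tasks on limited resources with by-product excretion; pathogens
    steal host CPU cycles and infect through task overlap. The package
    orchestrates paired control/invasion runs from a shared seed (plus
    control-control and contemporary-enrichment baselines), and quantifies
    invasion outcomes: lineage persistence and prevalence, diversity-change
    area-under-curve statistics, invader and community feature screening with
    Spearman correlations and rank-sum tests, random-forest prediction of
    invasion outcomes, and a substitutions-to-bacterial-generations calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    randomForest,
    rlang,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
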