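Package: comotraj
Title: Sex-Stratified Temporal Comorbidity and Disease Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale, sex-stratified analysis of disease
    progression from hospital registry data: hierarchical Bayesian Poisson
    estimation of diagnosis incidence with age standardization to the European
    Standard Population 2013, matched-cohort temporal diagnosis co-occurrence
    with directionality and relative-risk decision rules based on highest
    density intervals and regions of practical equivalence, sex-difference
    classification of directional pairs, and assembly of multi-step diagnosis
    trajectory networks. Includes a synthetic registry generator with known
    ground truth (planted directional pair effects, age- and sex-dependent
    incidence, seasonal admission volume, open outpatient contacts) so the
    whole pipeline is testable without access-restricted registry data, and a
    No-U-Turn Hamiltonian Monte Carlo sampler for the grouped hierarchical
    Poisson model family used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
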