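Package: gomsm
Title: Coarse-Grained Go-Model Simulation and Markov State Modelling of
    Protein-Protein Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for studying reversible protein-protein association
    with residue-level coarse-grained Go models and Markov state models
    (MSMs).  Provides a two-chain bead-spring simulator with Langevin
    (BAOAB) dynamics, spherical confinement and umbrella sampling along the
    chain-chain centre-of-mass distance; featurization (COM distance,
    pairwise distances, minimum RMSD), long-lived-contact filtering,
    time-lagged independent component analysis (TICA) and k-means
    discretization; reversible MSM estimation with PCCA+ metastable
    decomposition, mean first passage times, binding free energies and
    association/dissociation rate constants; a TRAM estimator that combines
    unbiased and umbrella-biased ensembles into one unbiased model; a
    bound-state cutoff optimizer based on indicator-autocorrelation
    relaxation times; and a variance-based (Sobol) sensitivity analysis of
    stationary probabilities that selects umbrella windows for focused TRAM
    refinement.  Synthetic two-chain complexes and discrete-chain oracles
    with closed-form thermodynamics are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
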