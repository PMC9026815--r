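Package: chirising
Title: 2D Ising Modelling of Competitive Enantiomer Adsorption on Achiral Surfaces
Version: 0.1.0
Authors@R:
    person("chirising", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Equilibrium modelling of competitive D-/L-enantiomer
    co-adsorption on achiral surfaces as a two-dimensional Ising system.
    Provides the saturated-lattice Hamiltonian with its effective chiral
    field, a Metropolis Monte Carlo sampler (compiled kernel) for
    equilibrium surface enantiomeric excess and full ees-versus-eeg
    isotherms, Onsager closed-form references for the spontaneous excess
    and critical temperature, Langmuir and competitive Langmuir baselines,
    an exact-enumeration oracle for small lattices, a chi-square
    grid-scan estimator of the homochiral-heterochiral exchange energy
    with cubic-minimum extraction, and a synthetic-data generator that
    emulates aspartic acid adsorption on Cu(111) at 460 K.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
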