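Package: psocluster
Title: Particle Swarm Optimization for Global-Minimum Atomic Cluster Geometries
Version: 0.1.0
Authors@R:
    person("psocluster", "developers", email = "psocluster@example.org",
           role = c("aut", "cre"))
Description: Stochastic global geometry optimization of small atomic clusters.
    Implements a modified particle swarm optimizer with stall-based
    convergence and a restart-to-self-consistency outer loop, together with
    simulated annealing and basin hopping comparators, over a uniform
    energy-backend contract.  Built-in Lennard-Jones and Morse pair
    potentials support desk-scale verification; a generic file-based adapter
    couples the search to any external quantum-chemistry engine through a
    templated input deck and log parsing.  Energy evaluations across the
    swarm are barrier-synchronized and deterministic for any worker count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
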