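Package: beedyn
Title: Honey Bee Colony Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartment model of honey bee (Apis mellifera) worker
    population dynamics with two behavioural castes, hive bees and
    foragers, coupled by brood eclosion and socially inhibited
    recruitment to foraging. Provides closed-form steady states,
    linear stability analysis, the bifurcation structure in the
    forager death rate (including the critical death rate above which
    the colony collapses), trajectory simulation and phase portraits,
    an optional recruitment-dependent precocious-forager mortality
    feedback, and demographic predictions (average age at onset of
    foraging and worker lifespan) at equilibrium and over finite
    observation windows. Includes a small command-line front-end for
    reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
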