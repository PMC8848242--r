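Package: sensdev
Title: Optimal Incremental Development and Sensitive Periods in
    Fluctuating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes optimal developmental policies for organisms that
    incrementally and irreversibly construct phenotypes while sampling
    imperfect cues to a two-state Markov environment that fluctuates
    across ontogeny.  Policies are obtained by exact stochastic dynamic
    programming (backward induction) over Bayesian belief states derived
    from the hidden-Markov forward algorithm.  From a solved policy the
    package enumerates likelihood-weighted developmental trajectories,
    mature-phenotype distributions, and simulated twin/adoption
    experiments that quantify phenotypic plasticity across ontogeny as a
    normalized phenotypic distance between clone pairs separated at each
    ontogenetic age.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
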