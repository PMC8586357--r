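Package: beselect
Title: Discrete-State Stochastic Modelling of Base-Editor Bystander Selectivity
Version: 0.1.0
Authors@R:
    person("Maintainer", "beselect", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemical-kinetic modelling of cytosine base editors with two
    editable cytidines (one target, one bystander) in the deaminase activity
    window. Implements the 15-state absorbing Markov chain of editing
    outcomes, closed-form first-passage probabilities for the four products
    (CTC, CTT, TTC, TTT), a reduced dimensionless parameterisation with
    Boltzmann mapping of binding free-energy perturbations onto unbinding
    rates, inference of site kinetics from Michaelis-Menten constants,
    least-squares fitting of the free rate ratios to observed editing
    fractions, selectivity landscapes over the mutation-induced binding
    perturbation, peak and design-window identification with
    candidate-mutation screening, Gillespie simulation as a stochastic
    cross-check, and a synthetic-data generator for multinomial editing
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
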