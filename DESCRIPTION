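Package: incentivecircuit
Title: Simulation of the Mushroom-Body Incentive Circuit for Memory Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a twelve-neuron rate model of the Drosophila mushroom
    body in which six dopaminergic neurons (DANs) and six mushroom body output
    neurons (MBONs) form reciprocal microcircuits that acquire, transfer and
    erase olfactory memories. Implements the dopaminergic plasticity rule
    (DPR), in which the synaptic change of a Kenyon-cell-to-MBON synapse is
    the product of a signed dopaminergic factor and the synapse's deviation
    from its resting weight, together with a reward-prediction-error
    alternative for comparison. Provides trial schedulers for acquisition,
    extinction, unpaired and reversal conditioning; an agent-based two-odour
    arena in which MBON outputs steer simulated flies and preference indices
    are computed from cumulative odour exposure; a high-resolution
    second-messenger (ER-Ca2+/cAMP) model that yields opposite associations
    for forward and backward pairings; and utilities for summarising
    trial-aligned calcium-imaging-style traces and running neuron
    silencing/activation screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
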