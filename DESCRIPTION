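Package: evoselect
Title: Evolutionary Wrapper Feature Selection for Volumetric Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiobjective evolutionary feature selection for binary
    case-control classification of volumetric brain-imaging features.
    Implements NSGA-II minimising (classification error, panel size)
    together with four single-objective metaheuristics (GA, ACO, SA, PSO),
    all driven by a wrapper fitness: a 20-10-5 multilayer perceptron
    trained with Levenberg-Marquardt backpropagation on an 80/20
    stratified split. Ships a p-value-ranked statistical baseline
    (Mann-Whitney rank-sum tests with Benjamini-Hochberg false discovery
    rate control), a synthetic cohort generator emulating correlated,
    right-skewed volumetric features in two groups, a replicated
    experiment harness with feature-frequency rankings, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
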