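Package: gliann
Title: Artificial Neuron-Glia Networks Trained with a Hybrid Glial-Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feed-forward classification networks in which every non-output
    neuron carries an artificial astrocyte. The astrocyte counts the neuron's
    activity over an m-iteration pattern cycle with a signed counter clamped
    at +/- n and multiplicatively potentiates (+25%) or depresses (-50%) the
    neuron's outgoing connection weights. Networks are trained with a
    two-phase hybrid method: unsupervised glial weight modulation while
    patterns pass through the network, followed by a real-valued genetic
    algorithm (fitness-proportionate selection, single-point crossover,
    mutation, elitist generational replacement) driven by the mean squared
    error. Includes the paired evaluation protocol used to compare plain
    neural networks against their neuron-glia counterparts: stratified 5x2
    cross-validation crossed with multiple initial-weight populations,
    steady accuracies, 95%-of-steady convergence times, performance indexes
    and Wilcoxon signed-rank comparisons, plus a synthetic Gaussian-cluster
    dataset generator so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
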