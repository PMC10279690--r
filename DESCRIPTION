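Package: hgflearn
Title: Hierarchical Gaussian Filter Modelling of Volatile Audio-Visual
    Associative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of a volatile audio-visual
    associative-learning task with dual (prediction and perception) reports.
    Generates task schedules with a 75% tone-rotation contingency that
    reverses every 16, 24 or 32 trials and embedded ambiguous probe trials;
    filters trial sequences through a three-level Hierarchical Gaussian
    Filter; couples the contingency beliefs to eight perceptual response
    models combining associative learning, priming and sensory memory; fits
    each model per run by MAP estimation with a Laplace approximation to the
    log model evidence; performs random-effects Bayesian model selection
    with protected exceedance probabilities and Bayesian model averaging;
    and provides behavioural scoring, group statistics, FDR-controlled
    correlations, parameter and model recovery studies, and export of
    trial-wise model quantities for event-related GLM designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
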