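Package: pcdraw
Title: Predictive-Coding Simulation of Drawing Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates how drawing completion depends on the precision of
    top-down (prior) and bottom-up (sensory) signals.  A variance-predicting
    recurrent network (a stochastic continuous-time RNN) learns 2-D pen
    trajectories of six shape classes by one-step-ahead prediction; its
    predictions are fused with sensory input by precision-weighted Bayesian
    integration.  Partial drawings are completed in two steps: the initial
    context state is inferred from a 30-step prefix by backpropagation
    through time with frozen weights (recognition), and the full 90-step
    trajectory is then generated, closed-loop for the unseen part.  The
    package provides a synthetic multi-stroke shape generator, the training
    and completion machinery, a factorial sweep over prior/sensory precision
    scaling factors, and evaluation of completion error and shape
    misinterpretation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
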