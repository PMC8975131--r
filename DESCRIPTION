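Package: fctbn
Title: Functional Continuous-Time Bayesian Networks for Disease
    Trajectory Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time Bayesian networks whose conditional
    transition intensities are Poisson regressions of subject-level
    risk factors with multiplicative parent effects.  Provides
    continuous-time Markov process primitives (intensity matrices,
    sojourn laws, sufficient statistics, closed-form maximum
    likelihood), joint structure and parameter learning by adaptive
    group-lasso penalised likelihood solved with a monotone FISTA
    proximal-gradient algorithm, Gaussian-mixture-model based
    sparsification and early stopping, exact inference by
    amalgamation and matrix exponentials (risk trajectories,
    multi-year condition prediction, AUC evaluation), and a Gillespie
    trajectory simulator that generates synthetic multimorbidity
    cohorts for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
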