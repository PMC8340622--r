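Package: coevolnet
Title: Continuous-Time Co-Evolution of Friendship Networks and Continuous Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of a directed friendship network and a continuous
    behavior variable (such as body mass index) observed as a two-wave panel.
    Network ties change one edge at a time at Poisson event times with
    exponential-family change-statistic weights; behavior follows a linear
    network-influence (spatial lag) Gaussian increment process between events.
    Provides a forward simulator of the joint process, the complete-data
    log-likelihood, a Metropolis-Hastings sampler that imputes the latent event
    history between the two panel waves, and a Monte Carlo EM maximum-likelihood
    estimator with parametric-bootstrap standard errors, together with a
    reference calculator for the discrete-choice actor-based (SAOM) behavior
    transition probabilities used as a comparison baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
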