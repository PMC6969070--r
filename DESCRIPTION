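Package: replisim
Title: Monte Carlo Simulation of Replication Regimes in Science
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an idealized scientific community to compare the cost
    (experiments run) and knowledge gain (true, interesting, replicated
    effects) of private versus public replication regimes. Supports
    discovery-oriented and theory-testing research, frequentist and Bayesian
    (Jeffreys-Zellner-Siow Bayes factor) inference, a generalized Pareto
    citation model with a logistic interest rule, and perturbations of the
    idealized community (p-hacking, optional stopping, fraud, absent
    effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
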