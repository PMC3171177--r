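Package: ppdsinfer
Title: Reverse Engineering Gene Regulatory Networks as Probabilistic
    Polynomial Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers stochastic discrete dynamic models of gene regulatory
    networks from short, discretized expression time courses. Observed state
    transitions over a prime finite field are fitted by all minimal polynomial
    dynamical systems consistent with the data; each minimal model corresponds
    to a cone of the Groebner fan of the ideal of the observed points, and the
    relative cone volumes, estimated by uniform sampling of weight-vector
    monomial orderings, become the model probabilities of the assembled
    probabilistic polynomial dynamical system (PPDS). Includes exact polynomial
    arithmetic over GF(p), Buchberger-Moller computation of reduced Groebner
    bases of ideals of points, stochastic state-space construction with fixed
    points, stabilities and connected components, weighted dependency graphs
    scored against reference wirings, synthetic data generation, quantile
    discretization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
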