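Package: azeopatch
Title: Azeotropy-by-Design for Patchy-Particle Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and validation of interaction matrices that embed
    azeotropic points in multicomponent patchy-particle mixtures, with
    multicomponent Wertheim first-order perturbation theory for phase
    diagrams (common-tangent coexistence and isochoric binodal tracing),
    and a Kern-Frenkel Monte Carlo engine (NVT and Gibbs ensemble with
    aggregation-volume-bias moves) that cross-validates the theory on the
    N2c8s2 cubic-diamond binary mixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
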