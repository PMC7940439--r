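Package: occusens
Title: First-Passage Modeling of Calcium Sensor Occupancy at the Presynapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and stochastic tools for diffusion-influenced
    reversible calcium binding to a vesicle-fusion sensor in a synaptic
    bouton. Computes the single-ion sensor occupancy probability P(t,r) by
    solving the switching-diffusion survival problem in the Laplace domain
    (with any number of mobile or fixed calcium buffers), inverts it either
    through an exact residue series over the relaxation spectrum or a
    fixed-Talbot contour, and extends the result to multi-ion influx,
    multi-site occupancy, and stochastic entry through voltage-gated calcium
    channels. A particle-based Brownian-dynamics simulator validates the
    analytical curves, and a five-state cooperative sensor model maps
    calcium transients to vesicle release rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
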