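Package: iplheat
Title: Monte Carlo Light Transport and ADI Heat Diffusion for Intense
    Pulsed Light Photoepilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates broadband intense pulsed light (IPL) photoepilation by
    coupling a weighted-packet Monte Carlo model of photon transport in a
    two-dimensional Cartesian skin model (melanin-rich epidermis, dermis,
    buried hair follicle) with an alternating-direction-implicit (ADI) solver
    for the transient heat-flow equation driven by the absorbed-energy matrix.
    Encodes the four commercial IPL temporal pulse categories (free discharge,
    square pulse, close pulse stacking, spaced pulse stacking) as trapezoidal
    sub-pulse trains and compares their epidermal and follicular heating at
    matched radiant exposure.
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
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
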