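Package: uhmwpeOptics
Title: Kubelka-Munk Inversion and Monte Carlo Photon Transport for
    Turbid Polymer Slabs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extraction of optical transport properties (absorption and
    scattering coefficients) of ultra-high molecular weight polyethylene
    (UHMWPE) and similar turbid slabs from integrating-sphere diffuse
    reflectance and transmittance spectra via the two-flux Kubelka-Munk
    model, together with derived quantities (total and effective
    attenuation, 1/e penetration depth, transport albedo) and an
    MCML-style Monte Carlo photon-packet simulator for a single
    homogeneous slab with Henyey-Greenstein scattering and Fresnel
    boundaries. Includes a synthetic spectrum generator emulating
    integrating-sphere measurements of pristine and gamma-irradiated
    UHMWPE, and pipeline helpers that invert, derive, simulate and
    cross-validate against the closed-form two-flux solution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
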