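Package: auxinring
Title: Polar Auxin Transport Patterning on a Ring of Provascular Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartment model of polar auxin transport on a periodic ring of
    provascular cells with apoplastic spaces between them. Cytosolic auxin is
    exported by polarly localized efflux carriers (PIN-type) and imported by
    homogeneously distributed influx carriers (AUX1/LAX-type) together with
    passive chemiosmotic uptake; apoplastic auxin diffuses between adjacent
    wall compartments. The package provides the coupled ODE system and its
    homogeneous steady state, numeric linear stability analysis with
    mode-by-mode dispersion relations and phase diagrams, a fixed-step
    fourth-order Runge-Kutta ensemble simulator, quantification of periodic
    auxin patterns (peak detection on the ring, incipient-maxima filtering,
    wavenumber and amplitude statistics), morphometric decomposition of
    vascular-bundle counts into spacing and cell-number contributions with an
    exact Wilcoxon rank-sum test, and synthetic-data generators for testing
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
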