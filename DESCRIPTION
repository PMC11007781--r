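Package: bistatus
Title: Bistatic Dual-Aperture Ultrasound Imaging and Vascular Strain
    Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, reconstruction and analysis tools for bistatic
    dual-aperture ultrasound imaging of a vessel cross-section. Two curved
    array probes insonify the same imaging plane with steered diverging
    waves; the package simulates channel data from a pulsating-vessel
    scatterer phantom with analytic ground truth, beamforms all four
    transmit/receive probe pairings by delay-and-sum, registers the probes
    automatically by maximizing trans-probe signal coherence, coherently
    compounds the bistatic images, estimates wall motion by coarse-to-fine
    speckle tracking with angular displacement compounding, and computes
    radial and circumferential wall strain together with image- and
    strain-quality metrics (generalized contrast-to-noise ratio, mean
    drift error, elastographic signal-to-noise ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
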