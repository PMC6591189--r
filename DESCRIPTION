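Package: lvpump
Title: Single-Beat Estimation of Left Ventricular Pumping Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the systolic pumping mechanics of the left ventricle
    (maximal systolic elastance E_max and theoretical maximum flow Q_max of
    the elastance-resistance model) from a single measured left-ventricular
    pressure pulse together with cardiac output, without measured aortic
    flow or occlusion-measured isovolumic pressure.  The isovolumic pressure
    curve is estimated by non-linear least squares from the ejecting-beat
    pressure; an assumed triangular aortic flow is located from the
    harmonic-filtered fourth-order time derivative of the pressure and
    calibrated by cardiac output; the pressure-ejected-volume loop yields
    the tangent end-systolic elastance E_es.  Includes a time-varying
    elastance plus three-element windkessel simulator of rat-scale beats
    with known ground truth, and a validation harness (linear regression
    and Bland-Altman agreement) comparing pressure-only estimates against
    measured-flow estimates on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
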