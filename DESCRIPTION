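Package: pitcorr
Title: Continuum-Damage Pitting Corrosion Simulation and Response-Surface
    Calibration for Biodegradable Magnesium Implant Coupons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based continuum damage mechanics (CDM) simulator of
    pitting corrosion for biodegradable Mg-Zn-Ca implant coupons immersed
    in simulated body fluid, together with a response-surface-methodology
    (RSM) calibration workflow.  A disc coupon is discretised into cubic
    elements; each element carries a scalar damage variable driven by a
    Weibull-distributed pitting parameter, and fully damaged elements are
    removed from the mesh while their face neighbours inherit an
    accelerated pitting parameter.  Mass-loss curves are extracted,
    aligned with gravimetric immersion data on a dimensionless time axis,
    and the four pitting parameters (gamma, psi, beta, Ku) are calibrated
    by a three-level Box-Behnken design, a chi-square discrepancy, a full
    quadratic response surface, and constrained minimisation.  Includes a
    packaged Mg-1.2Zn-0.5Ca immersion dataset, a pseudo-experiment
    generator for parameter-recovery studies, VTK export of damage
    fields, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
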