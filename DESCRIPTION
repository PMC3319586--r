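Package: avfplan
Title: Patient-Specific Lumped-Parameter Simulation for Arteriovenous
    Fistula Surgery Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts immediate postoperative brachial artery flow for
    candidate arteriovenous fistula configurations (radiocephalic,
    brachiocephalic, brachiobasilic) from routine preoperative
    measurements.  The upper-extremity arterial and venous circulation is
    represented as a zero-dimensional transmission-line network of lumped
    resistance-inertance-compliance segments with three-element windkessel
    terminals and a flow- and angle-dependent nonlinear anastomosis
    element.  Model personalization uses duplex ultrasound diameters,
    brachial distensibility, mean arterial pressure and magnetic-resonance
    mean flows.  A baroreflex iteration restores the preoperative mean
    aortic pressure after virtual fistula creation, input-parameter
    uncertainty is propagated by Latin-Hypercube Monte-Carlo sampling, and
    a clinical decision rule (400-1500 ml/min flow window with
    radiocephalic > brachiocephalic > brachiobasilic preference) turns the
    predicted flow distributions into a surgical recommendation.  A
    synthetic-patient generator emulates the full measurement record so
    the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
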