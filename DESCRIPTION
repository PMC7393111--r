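Package: secforce
Title: Kinetic Dissection of Sec Translocation and Motor-Force Inference
    from Single-Molecule Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the mechanical force generated by the SecA
    translocation motor by combining two measurements on the same substrate
    protein: (1) real-time split-luciferase translocation traces, dissected
    with a closed-form kinetic model into unfolding, translocation and
    incapacitation rates, and (2) optical-tweezers force-ramp rupture data,
    analysed with a binless maximum-likelihood fit of a Kramers-like
    (Dudko-Hummer-Szabo) force-dependent rate law to obtain folded-state
    lifetimes as a function of force. Matching the translocation-derived
    unfolding time to the force-dependent lifetime curve yields the
    equivalent constant force applied by the motor, with Monte-Carlo
    uncertainty propagation. Includes worm-like chain contour-length
    bookkeeping, an exact rupture-force sampler, the classical binned
    lifetime transform, distribution-shape diagnostics for multi-barrier
    unfolding, and synthetic-data generators for both experiment types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
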