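Package: dioxhop
Title: Surface-Hopping Dynamics and Trajectory Statistics for Dioxetane
    Thermolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale study of the chemiexcitation dynamics of
    trans-3,4-dimethyl-1,2-dioxetane thermolysis. Provides an analytic
    multi-state model of the singlet/triplet potential-energy landscape
    (entropic trap, excited-state dissociation ridges, weak spin-orbit
    coupling), a fewest-switches surface-hopping engine with energy-based
    decoherence operating in the diagonal (spin-mixed) representation,
    Boltzmann-sampled initial conditions rescaled to a fixed kinetic
    energy, and the full trajectory-statistics pipeline: dissociation
    times and half-times, frustrated-dissociation counting, transition
    count matrices and state residence times, chemiexcitation quantum
    yields, population time series, dihedral-angle unwrapping, and
    endpoint-subrange (RLSE) feature classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
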