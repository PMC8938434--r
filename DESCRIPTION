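Package: fgphase
Title: Quantitative Analytics for Phase-Separated FG-Repeat Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of liquid-liquid
    phase separation of intrinsically disordered FG-repeat (nucleoporin)
    domains. Implements extraction of residue-specific rotational
    correlation times from TRACT (TROSY for rotational correlation time)
    15N relaxation series with Monte Carlo error propagation, exponential
    FRAP recovery fitting with translational diffusion coefficients,
    detection of phase-transition temperatures from dynamic light
    scattering temperature ramps and assembly of LCST phase diagrams,
    closed-form Stokes-Einstein(-Debye) hydrodynamic predictions from
    repeat sequences, chemical-shift-perturbation and NOESY contact
    bookkeeping for perfectly repetitive sequences, and critical
    concentration and partition-coefficient analytics for centrifugation
    and permeation assays. Includes seeded synthetic-data generators that
    emulate each instrument's acquisition design for validation and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
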