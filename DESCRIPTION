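Package: cuprelax
Title: Relaxometric, EPR and ENDOR Analysis of Cu(II) MRI Probe Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint Solomon-Bloembergen-Morgan / Swift-Connick analysis of
    variable-field 1H relaxivity (NMRD) profiles and variable-temperature
    17O NMR data for S = 1/2 copper(II) complexes, including the Freed
    outer-sphere translational-diffusion model, Eyring/Arrhenius temperature
    laws and base-catalysed prototropic exchange. Companion spin-Hamiltonian
    tools simulate rigid-limit powder and fast-motion CW-EPR spectra of
    63/65Cu centres (second-order perturbation theory with an exact
    diagonalization oracle), extract rotational correlation times from
    room-temperature spectra, compute first-order Davies ENDOR spectra with
    orientation selection, and estimate metal-proton distances in the
    point-dipole approximation. Seeded synthetic-data generators emulate
    every dataset type with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
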