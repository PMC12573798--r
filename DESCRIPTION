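Package: tdfrs
Title: Analysis of Transient-Grating Thermodiffusion Experiments on Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thermal diffusion forced Rayleigh scattering (TDFRS)
    experiments on protein solutions. Provides the closed-form two-mode
    (thermal + concentration) heterodyne signal model, nonlinear
    least-squares extraction of relaxation times and steady-state amplitude
    from averaged heterodyne traces, conversion to transport coefficients
    (mass diffusion D, thermal diffusivity D_th, thermal diffusion
    coefficient D_T, Soret coefficient S_T), fitting of the empirical
    exponential temperature law for S_T with its sign-change temperature,
    the temperature-sensitivity statistic Delta S_T between two
    temperatures, and its correlation with alpha-helical content across
    solution conditions. Includes sequence-level protein property
    calculations (molecular weight, extinction coefficient, net charge and
    isoelectric point by Henderson-Hasselbalch titration), buffer speciation
    and an immobilized-water hydration index, and seeded synthetic-data
    generators (RK4 two-mode integration, Soret point sets, condition sets)
    so every stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    MASS,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
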