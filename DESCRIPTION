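Package: losartanpkpd
Title: Genotype-Stratified Pharmacokinetics and Pharmacodynamics of Losartan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mechanistic five-compartment model of oral losartan and its
    active metabolite E-3174, with sinusoidal gastric emptying, enterocyte
    efflux governed by ABCB1 genotype and time-delayed hepatic conversion
    governed by CYP2C9 genotype. Provides non-compartmental summaries
    (Cmax, tmax, terminal half-life, AUC, apparent oral clearance), an E-max
    coupling from metabolite exposure to an AT1-receptor-blocking
    coefficient, seeded global parameter estimation with identifiability
    profiling and local sensitivity coefficients, virtual-population
    simulation of between-subject variability, gated nonparametric group
    comparison, and a synthetic-data generator for sparse two-analyte
    concentration-time designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    car,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
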