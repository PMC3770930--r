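Package: depspec
Title: Dual-Cycle Dielectrophoretic Collection-Rate Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing nanoparticle dielectric properties from
    pulsed dielectrophoretic (DEP) collection kinetics. Implements the real
    part of the Clausius-Mossotti (CM) polarizability spectrum with crossover
    analysis and a piecewise-linear approximation; a dual-cycle (control plus
    probe) amplitude-modulated DEP collection and release simulator with a
    one-dimensional drift-diffusion (Fokker-Planck) oracle; extraction of
    initial collection rates and control/probe rate ratios from time traces;
    bivariate Newton-Raphson least-squares fitting of the CM spectrum to rate
    ratios yielding nanoparticle conductivity and a scale factor; and a
    Monte-Carlo comparison of the rate-ratio estimator against the classical
    crossover-frequency method. Includes a command-line interface and a
    synthetic fixture generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
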