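Package: lvtumor
Title: Tumor-Host Dynamics with the Competitive Lotka-Volterra Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tumor-host interaction as a two-species
    competitive Lotka-Volterra system. Provides regime classification from
    kinetic parameters via linear stability analysis, a Dulac certificate
    ruling out closed orbits, a one-dimensional potential (particle) reduction
    with characteristic frequencies, therapy-dose planning for continuous
    treatment with proportional or constant (additive) effect including
    saddle-node bifurcation thresholds, stroboscopic characterisation of
    periodically forced dynamics, Lyapunov-exponent spectra of the forced
    system by tangent-vector renormalization, and least-squares fitting of the
    model's tumor component to volume-versus-time growth curves. A synthetic
    data generator produces regime fixtures and noisy tumor-volume series for
    testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
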