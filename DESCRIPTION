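Package: svifwi
Title: Stochastic Variational Full-Waveform Inversion for Ultrasound Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-dimensional acoustic full-waveform inversion (FWI) for
    ultrasound computed tomography with a no-cost per-pixel uncertainty
    estimate. The inversion is posed as stochastic variational inference
    under a mean-field Gaussian approximating distribution: every iteration
    one model is sampled by the reparameterisation trick, a single
    adjoint-state gradient is computed with a finite-difference time-domain
    wave solver, and that gradient simultaneously updates the per-pixel mean
    (the image) and the per-pixel signed standard deviation (the uncertainty)
    at the cost of one elementwise product. Includes phantom generators,
    synthetic acquisition geometries, controlled data corruptions, and
    image-quality diagnostics (SSIM, variance-trend summaries, failure flags,
    artefact localisation) that use the variance image as an online monitor
    of reconstruction quality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
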