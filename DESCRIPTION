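Package: freshir
Title: Chemometric Analysis of Single-Fibre FTIR Microspectra for Fish Freshness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the postmortem age of fish muscle from
    single-fibre Fourier-transform infrared (FTIR) microspectra. Implements
    the full chemometric chain: iterative polynomial (ModPoly) baseline
    correction, fingerprint-region cropping and vector normalisation;
    principal-component discriminant analysis (PC-DA) with Mahalanobis
    group-membership probabilities and a discriminant contribution vector
    back-projected to wavenumber space for biomarker identification;
    cross-validated radial-kernel support-vector classification of
    postmortem day; t-SNE visualisation; peak-intensity, ratiometric and
    ANOVA/Tukey marker statistics with spectra-to-physicochemistry
    correlation. A seeded synthetic spectrum generator emulating
    hierarchical fish/fibre variability, band-level aging effects, baseline
    drift and noise makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
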