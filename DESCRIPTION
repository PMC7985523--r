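Package: lsdox
Title: Learned Spectral Decoloring for Photoacoustic Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise estimation of blood oxygen saturation (sO2) from
    multispectral photoacoustic initial-pressure spectra by learned spectral
    decoloring (LSD): a fully connected regressor trained purely on simulated
    tissue phantoms, together with a linear-unmixing baseline and a full
    in-silico evaluation suite. Includes seeded generators for three synthetic
    tissue domains (generic tissue, blood flow phantom, human forearm), a
    wavelength-resolved optical forward model (deterministic layered fluence
    plus a voxel Monte Carlo photon transport code), spectra extraction with
    CNR and amplitude masking, sum-to-one normalization, error summaries, and
    the Severinghaus oxygen dissociation curve for reference conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
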