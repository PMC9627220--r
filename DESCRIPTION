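Package: specfx
Title: Spectrum-Effect Relationship Screening for Herbal Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectrum-effect relationship modelling of herbal
    medicine fingerprints. Builds and validates common-peak matrices from
    LC-MS peak tables (retention-time matching, internal-standard relative
    metrics, dispersion and linearity QC, cosine fingerprint similarity,
    legacy TXT export), converts bioassay readouts (DPPH, FRAP, CCK-8,
    wound healing, transwell) into orientation-normalized activity tables,
    and screens candidate active constituents by three chemometric routes:
    Deng's grey relational analysis, NIPALS partial least squares
    regression with VIP scores and leave-one-out Q2, and a backpropagation
    neural network with mean-impact-value perturbation. Per-endpoint
    selections are combined by set intersection into a consensus, and a
    seeded synthetic-data generator with planted active peaks grades
    recovery end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
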