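Package: radioknot
Title: Radioligand Pharmacology, Biodistribution and MIRD Dosimetry for a
    177Lu-Labelled Integrin Alpha-v-Beta-6 Knottin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for preclinical evaluation of a
    177Lu-DOTA integrin alpha-v-beta-6 cystine knot peptide in pancreatic
    cancer models. Fits one-site saturation and competition radioligand
    binding models to gamma-counter plate data and converts fitted maxima
    to receptor sites per cell; fits four-parameter logistic radiation
    dose-response curves and performs delta-delta-Ct qPCR normalisation;
    reduces per-animal gamma-counter biodistribution data to
    decay-corrected percent injected activity per gram and organ
    time-activity curves; extrapolates mouse uptake to the human reference
    adult by allometric mass and time scaling; and computes organ absorbed
    doses and an ICRP-weighted effective dose from time-integrated
    activity coefficients with an open MIRD-style S-value engine. Includes
    seeded synthetic-data generators emulating each assay for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
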