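Package: craniosex
Title: Morphoscopic Cranial Sex Estimation and Multi-Rater Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for virtual sex estimation from ordinal cranial
    morphoscopic trait scores (glabella, mastoid process, supra-orbital
    margin). Implements the Walker logistic discriminant (equation 2) with
    male/female posterior probabilities, tie-corrected Kendall's coefficient
    of concordance and Fleiss' kappa for multi-observer agreement with
    Landis-Koch interpretation bands, per-observer classification accuracy
    reports against recorded sex, a latent-threshold simulator of
    multi-observer ordinal scoring with known ground truth, and a
    reproduction report for the embedded study tables of eight observers
    scoring twenty crania.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
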