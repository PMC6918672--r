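Package: lfpdecode
Title: Decoding Biological Outcomes from Corticostriatal Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spectral feature extraction and penalized-regression decoding for
    multichannel local field potential (LFP) recordings. Converts raw
    four-channel corticostriatal recordings (bilateral medial prefrontal
    cortex and nucleus accumbens shell) into 60 normalized band power and
    coherence features, fits lasso models of binary (sex, estrous phase) and
    continuous (alcohol intake, g/kg) outcomes under repeated fourfold
    cross-validation, and evaluates information content against random-label
    and rat-level group-permutation null distributions, with exhaustive
    single-feature AUC and R-squared ranking. Includes a synthetic oscillatory
    cohort simulator with controllable band power, inter-channel coherence,
    1/f background, artifacts, and per-rat random effects, so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    pROC,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
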