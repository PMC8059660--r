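Package: soundstab
Title: Sound-Group Stability and Vocal Iconicity in Lexical Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the relative evolutionary stability of articulatory
    sound groups from cross-linguistic wordlists and relates it to vocal
    iconicity and first-language acquisition order. Provides IPA
    segmentation and articulatory feature classification, per-language
    information-content models that down-weight recurrent inflectional
    material, PMI-based sound-correspondence learning with global sequence
    alignment, homologue (cognate) clustering, the SSt sound-group
    stability statistic with replacement-rate and information weighting and
    a four-way outcome decomposition, Bayesian odds-ratio iconicity coding
    with a ROPE decision rule, an L1 acquisition-order feature join, and
    stratified linear regression. A lexical-evolution simulator with known
    ground truth supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    stringi,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
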