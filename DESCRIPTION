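Package: perioloss
Title: Keypoint-Based Measurement and Staging of Radiographic Periodontal Bone Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures radiographic periodontal bone loss (PBL) on rectangular
    molar crops from panoramic radiographs and assigns the corresponding
    periodontal stage. Implements a three-component pipeline: a statistical
    keypoint prior built by fitting one-dimensional probability functions to
    the twelve coordinates of six anatomical landmarks (mesial and distal
    cementoenamel junction, alveolar crest and root apex), a compact
    depthwise-separable convolutional network that refines sampled prior
    predictions conditioned on the molar image, and a rule-based geometric
    calculation of per-side PBL percentage and stage. Also provides the full
    rater-evaluation scheme (one-vs-rest diagnostic counts, per-stage metrics,
    macro/weighted/micro averages, two-way intraclass correlation) and a
    synthetic molar-crop generator with known keypoint geometry for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    fitdistrplus,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'annotations.R'
    'evaluation.R'
    'nnet.R'
    'perioloss-package.R'
    'pipeline.R'
    'prior.R'
    'refiner.R'
    'staging.R'
    'synthgen.R'
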