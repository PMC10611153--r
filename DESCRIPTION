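Package: fnirsEmotion
Title: Emotion Classification from Prefrontal fNIRS Hemodynamics with a
    CNN-Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multi-channel functional near-infrared
    spectroscopy (fNIRS) recordings for ternary emotion recognition (joy,
    neutral, sad). Converts dual-wavelength (735/850 nm) optical-density
    changes to oxy-/deoxy-hemoglobin concentration changes via the Modified
    Beer-Lambert Law, removes cardiac, respiratory and Mayer-wave noise with
    a zero-phase low-pass filter, assembles 9600 x 16 trial matrices and
    segments them into labeled windows, and classifies windows with a hybrid
    1D-CNN + multi-head self-attention (Transformer) network trained by SGD,
    alongside eight reference classifiers. Classifiers are compared across
    repeated runs with a Friedman test, Kendall's W and Cohen's f. A
    block-design hemodynamic simulator with class-dependent responses and
    physiological noise bands makes the whole pipeline testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    e1071,
    class,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'fnirsEmotion-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'mbll.R'
    'io.R'
    'filter.R'
    'preprocess.R'
    'simulate.R'
    'autodiff.R'
    'model.R'
    'baselines.R'
    'evaluate.R'
    'pipeline.R'
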