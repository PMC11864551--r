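Package: ethoaccel
Title: Behaviour Classification from Low-Frequency Triaxial Accelerometer
    Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying animal behaviour from low sampling rate
    (1 Hz) triaxial accelerometer streams such as those produced by
    wildlife ear tags. Implements the jerk filter and overall dynamic body
    acceleration (ODBA), overlapping-window majority labelling,
    moment-based and periodogram feature extraction, random-forest
    behaviour classification with per-class sensitivity, specificity and
    balanced accuracy, Cohen's kappa, a window-size sweep experiment, and
    a behaviour-labelled acceleration simulator so every pipeline stage
    can be exercised without field data.
License: MIT + file LICENSE
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    nnet,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
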