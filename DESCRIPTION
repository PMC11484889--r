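Package: finchvocal
Title: Female Call Interactions with Juvenile Zebra Finch Song Practice and
    HVC Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies of female zebra finch calls during
    juvenile song practice and their neural correlates in the premotor
    nucleus HVC. Provides envelope-based syllable segmentation and song-bout
    assembly, call-to-song attribution and call-ratio statistics,
    developmental trend regression and learner classification, intracellular
    membrane-potential analysis (spike detection, permutation-based spiking
    precision, spike clipping and subthreshold correlation, perturbation
    responsiveness), extracellular unit quality control and population
    playback-response summaries, nested mixed-model comparison wrappers, and
    a synthetic-data generator with known ground truth so every stage is
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
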