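Package: taskguide
Title: Guidance Engine and Scoring Instruments for a Vision-Based
    Cognitive Prosthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the guidance logic of a camera-based cognitive
    prosthesis for multi-step activities of daily living: YAML-configured
    task modules, rolling-average stabilisation of object-detection
    streams, a step state machine with positive and corrective feedback
    and a five-level cue hierarchy, session timing capture, and three
    clinical scoring instruments (a per-step daily task completion score,
    a modified Executive Function Performance Test, and the System
    Usability Scale).  A synthetic-participant simulator and a
    detection-quality evaluation harness allow the whole pipeline to run
    and be tested end-to-end without a camera or a trained vision model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
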