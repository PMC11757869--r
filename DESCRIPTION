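Package: echonav
Title: Reinforcement-Learning Probe Navigation over Cardiac Detection
    Confidence Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-world search for the ultrasound probe position that images a
    heart component most clearly, driven by per-cell object-detection
    confidence scores. Provides a synthetic generator for chest confidence
    maps with rib-shadow attenuation and a sternal dead band, a nine-action
    grid environment with reward shaping that penalises stopping at local
    confidence maxima, a deep Q-network trained with experience replay, a
    deterministic path-generation layer that avoids revisits and recovers
    from zero-confidence stops, a serpentine full-coverage baseline, and an
    evaluation harness (loss-of-confidence rate, Cohen's d effect sizes,
    outcome categorisation, subject-wise cross-validation and parameter
    sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
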