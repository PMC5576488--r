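Package: ripplecontent
Title: Classification of Hippocampal Sharp-Wave Ripple Content and
    Prefrontal Modulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for multi-tetrode hippocampal-prefrontal
    recordings that separates sharp-wave ripple (SWR) reactivation into
    movement- versus immobility-associated content. Provides adaptive SWR
    detection from the consensus ripple-band (150-250 Hz) envelope with an
    empirical mode-mirrored noise threshold, classification of CA1 units
    into movement-associated (MAP) and immobility-associated (IAP) place
    cells, SWR content classification with independence statistics and
    permutation coactivity z-scores, prefrontal SWR-modulation indices with
    circular-permutation significance tests, spike-train correlation
    measures, and a fully parameterised synthetic session generator with
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, signal, data.table, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
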