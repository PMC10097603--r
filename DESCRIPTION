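Package: claustra
Title: Bilateral Claustrum Sleep Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and bilateral matching of sharp negative (SN) field
    potential events in claustrum local field potential recordings of
    sleeping reptiles, together with sliding lagged cross-correlation,
    instantaneous-leadership scoring, dominance- and sleep-state
    segmentation, and episode-level statistics. Includes a synthetic-night
    generator that emulates the statistical structure of bilateral
    claustrum recordings (SN trains with skewed inter-event intervals,
    inter-claustral lags, sharp-wave ripples during slow-wave sleep,
    isthmic nucleus channels, dominance switching, and a unilateral-lesion
    mode) so that every analysis stage can be validated against ground
    truth without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
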