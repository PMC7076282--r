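Package: neurocal
Title: Quantification of Calcium Transients and Store-Operated Calcium
    Entry in Differentiating Human Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for somatic calcium-imaging recordings from
    human neural stem cell derived cortical neurons. Detects spontaneous
    Fluo-4 calcium transients with a first-derivative threshold (quiet-region
    mean + k x SD), counts spikes per 4-minute window, measures and bins
    transient amplitudes, and assesses treatment abolition (TTX, nimodipine).
    Converts Fura-2 340/380 ratio recordings to absolute cytosolic calcium
    concentration with per-cell Grynkiewicz calibration (Rmin from EGTA, Rmax
    from ionomycin, per-cell scaling factor from the 380 nm channel) and
    quantifies basal calcium, thapsigargin-evoked store release and
    store-operated calcium entry (SOCE). Includes the accompanying expression
    arithmetic (2^-deltaCt relative expression, log2 fold-change threshold
    classification with overlap counts, calcium-panel column z-scores, marker
    positivity percentages) and a forward simulator for both imaging
    modalities with exact ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
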