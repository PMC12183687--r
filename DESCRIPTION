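Package: fscvephys
Title: Dual-Mode Neurochemical and Electrophysiological Recording Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for concurrent fast-scan cyclic voltammetry
    (FSCV) and electrophysiology recorded from carbon-fiber microinvasive
    probes. Extracts dopamine concentration changes from FSCV color plots by
    event-referenced background subtraction and principal component
    regression with Q-residual and movement-correlation gating; removes the
    periodic FSCV scan artifact from concurrent wide-band electrophysiology
    by spectral or time-domain interpolation; computes beta-band local field
    potential power envelopes, threshold-detected spikes, peristimulus time
    histograms and interspike-interval distributions; synchronizes the two
    acquisition clocks via shared event codes and builds condition-split
    event-aligned trial averages. Includes closed-form probe mechanics
    (layered-cylinder flexural rigidity, Euler buckling, cantilever
    deflection) and a fully synthetic session generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
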