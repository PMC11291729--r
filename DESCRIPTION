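Package: patchquant
Title: Quantification of Single-Channel and Whole-Cell Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying ion-channel activity from patch-clamp
    recordings: amplitude histograms with Gaussian-mixture fits, unitary
    current and slope conductance from single-channel current-voltage
    relations, half-amplitude threshold idealization, open-probability
    statistics (Popen, NPo) with multi-channel and multi-level corrections,
    whole-cell current density, monoexponential activation time constants,
    and ramp-based reversal potentials. Includes an event-driven
    continuous-time Markov-chain simulator of channel gating with ohmic
    current rendering, Gaussian baseline noise and Bessel low-pass
    filtering, so every analysis stage can be validated by parameter
    recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
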