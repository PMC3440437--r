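Package: spikedecoder
Title: Threshold-Template Neural Decoding with Viterbi Trajectory Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes a discretized behavioral state (such as position on a
    linear track) from multichannel spike trains using a two-stage scheme
    designed for severely power-constrained implanted hardware. The internal
    stage counts spikes in fixed windows with saturating b-bit counters and
    compares the counts against per-state threshold templates using only
    logical conjunction, emitting one bit per state per window. Templates are
    learned from in-state versus out-of-state spike-count histograms under
    global sensitivity and positive-predictive-value minima. The external
    stage smooths the binary output with a Viterbi decoder whose emission
    model is an empirical confusion matrix and whose transition prior is a
    diffusion-like kernel that broadens with elapsed time between informative
    outputs. Includes single-threshold spike detection with robust noise
    estimation, a synthetic place-cell data generator, and evaluation tools
    (classification metrics, trajectory correlation, compression-factor and
    operation-count models).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
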