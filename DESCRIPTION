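Package: meetsemg
Title: Mixture-of-Experts Extra-Trees Classification of Surface EMG Hand
    Gestures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for surface electromyography (sEMG) hand
    gesture recognition: synthetic multichannel sEMG generation emulating a
    block-wise acquisition protocol, Butterworth bandpass and 50 Hz notch
    filtering, overlapping-window segmentation, a canonical set of seventeen
    time- and frequency-domain window features, and the MEET classifier --
    a mixture of class-partitioned extremely randomized tree experts fused
    with a full-class gating ensemble through an elementwise (Hadamard)
    product. Includes confusion-matrix metrics, stratified model comparison,
    and paired t-tests for classifier accuracy comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
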