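Package: quakecall
Title: Before/After Analysis of Blue Whale Calling Around Earthquakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether blue whale calling activity changes
    around episodic noise events such as earthquakes, using passive acoustic
    monitoring data. Implements a spectrogram template-correlation detector
    for downswept D calls, a band-energy-ratio song intensity index for the
    New Zealand blue whale song chorus, earthquake catalog filtering
    (magnitude, bounding box, 8-hour isolation, stratified weekly sampling),
    relative received-level measurement in dBFS, a multi-scale before/after
    window design with a matched null-period control, paired t-tests and
    linear models of the change in calling, and a synthetic scenario
    generator producing hydrophone recordings with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
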