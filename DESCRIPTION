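Package: afdfmap
Title: Dominant-Frequency Mapping of Atrial and Body-Surface Signals in
    Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spectral analysis pipeline for multichannel atrial
    electrogram and body-surface mapping recordings in atrial
    fibrillation. Computes per-window Welch power spectra on a fixed
    0.05 Hz grid, dominant frequency (DF) in the 4-10 Hz band, the
    organization index (OI), an F-ratio peak-significance test with
    harmonic classification, highest-DF (HDF) areas under OI
    thresholding, paired body-surface minus endocardial HDF differences
    with 0.5 Hz binning and exponential curve fitting, and HDF
    atrial-area distribution comparisons. Includes QRS-T far-field
    cancellation by average-beat template subtraction, channel quality
    control against mains contamination, polyphase resampling and
    zero-phase moving-average band-pass filtering, EDF/BDF and
    delimited-matrix input, and a synthetic atrial-source plus
    volume-conductor simulator providing full ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
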