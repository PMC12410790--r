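Package: camsnr
Title: Camera Noise Calibration and Signal-to-Noise Budgeting for
    Quantitative Fluorescence Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of the EMCCD/sCMOS image-formation noise
    chain (photon shot noise, dark current, clock-induced charge,
    electron-multiplication excess noise, read noise, digitization) and the
    matching calibration estimators that recover each camera parameter from
    dark-frame and photon-transfer frame suites: read noise from
    zero-exposure dark frames, the gray-value/electron conversion ratio from
    mean-variance statistics, dark current from an exposure series,
    electron-multiplication gain from intensity ratios, and clock-induced
    charge from gained dark frames. Includes signal-to-noise metrics for
    fluorescence images: theoretical SNR budgets, excess background noise
    relative to matched dark frames, gain-normalized noise floors, and
    camera-independent SNR of cell regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    jsonlite,
    yaml,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
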