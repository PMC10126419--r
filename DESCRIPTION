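Package: chamberbeat
Title: Chamber-Specific Heartbeat Phenotyping for Zebrafish Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac phenotypes of embryonic zebrafish from
    fluorescence or brightfield heartbeat recordings. From an image series the
    package detects the heart region, segments atrium and ventricle with
    intensity thresholds that exclude the atrioventricular canal, derives
    per-chamber heartbeat traces from summed pixel intensities and chamber
    areas, and estimates beat frequency both by iterative sine fitting and by
    the dominant harmonic of the discrete Fourier transform. Per-fish outputs
    cover heart rate, heart size, dilation and contraction extremes,
    contractility, approximate ejection fraction, arrhythmia and
    atrioventricular conduction scores, and the atrium-to-ventricle beat
    ratio. Screen-level helpers perform DMSO fold-change normalization,
    z-score hit calling at 90 or 95 percent confidence, a composite toxicity
    score, and validation correlations with outlier exclusion. A synthetic
    beating-heart video generator with analytic ground truth makes every
    stage testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    pracma,
    mgcv,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
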