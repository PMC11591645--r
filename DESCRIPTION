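Package: boneraman
Title: Raman Spectral Analysis of Human Bone for Post-Mortem Interval Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for classifying the post-mortem interval (PMI)
    of human bone from Raman spectra. Implements spectrum input/output and
    resampling, the pretreatment chain used in forensic bone chemometrics
    (point reduction, Savitzky-Golay smoothing, area normalization),
    baseline-corrected band metrics (peak height, intensity, trapezoidal and
    intensity-sum areas, FWHM), a six-marker bone-quality panel
    (phosphate intensity, crystallinity index, mineral-to-matrix ratio,
    carbonate-to-phosphate ratio, mineral carbonate content, amide I
    intensity), per-marker one-way ANOVA with pairwise class contrasts and
    significance star coding, windowed principal component analysis over
    diagnostic wavenumber regions, and a fluorescence-dominance quality gate.
    A synthetic bone-spectrum generator emulating a handheld spectrometer and
    a Raman microscope makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
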