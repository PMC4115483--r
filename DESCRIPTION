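Package: tonguetrack
Title: Tongue Contour Tracking and Articulatory-Acoustic Analysis for
    Midsagittal Vocal-Tract MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks the tongue surface in midsagittal vocal-tract MRI frames
    with a greedy active contour seeded by morphological preprocessing of the
    dark oral cavity, measures articulatory parameters (tongue tip and tongue
    body constriction locations, lip aperture) relative to the palatal plane,
    estimates vowel formant frequencies by linear-predictive analysis of
    matching audio recordings, and correlates the articulatory and acoustic
    measurements. Ships a synthetic midsagittal phantom and vowel synthesizer
    with known ground truth so the whole pipeline is testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    signal,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
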