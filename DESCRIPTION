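Package: whiskvib
Title: Flow-Induced Vibration Analysis and Cross-Sectional Morphometry of Pinniped Whiskers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying flow-induced vibrations of pinniped vibrissae
    (whiskers). Generates synthetic whisker phantoms, laser-vibrometer style
    velocity recordings, and multi-subject study tables with known ground
    truth; computes cross-sectional morphometry (area, maximum and minimum
    caliper width, principal-axis angle, eccentricity) along voxelized whisker
    volumes; extracts peak frequency and velocity from averaged amplitude
    spectra; predicts vortex-shedding frequency from an empirical
    Strouhal-Reynolds relation; and runs mixed-design repeated-measures ANOVA
    with Tukey post-hoc comparisons across species and angle of attack. An
    end-to-end pipeline ties the stages together into a reproducible
    synthetic study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
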