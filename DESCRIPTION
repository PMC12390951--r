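Package: neorhythm
Title: Simulation and Analysis Pipeline for Neonatal fNIRS Studies of Auditory Beat Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design rhythmic and arrhythmic auditory stimulus sets,
    simulate dual-wavelength functional near-infrared spectroscopy (fNIRS)
    recordings of premature neonates under a block design, preprocess raw
    intensities into quality-controlled oxyhemoglobin epochs (optical density
    conversion, band-pass filtering, modified Beer-Lambert law, motion-artifact
    and trial-rejection rules), and run the group statistics used in
    developmental auditory neuroscience: rising-slope metrics, temporal and
    spatial cluster-based permutation tests, and repeated-measures ANOVA over
    regions of interest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    emmeans,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
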