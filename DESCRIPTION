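Package: epiT1
Title: Quantitative T1 Mapping and Distortion Matching for Two-Inversion
    Segmented 3D-EPI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward Bloch simulation, protocol optimization and quantitative
    T1 mapping for two-inversion Look-Locker segmented 3D-EPI structural
    acquisitions, as used for distortion-matched structural reference data in
    high-resolution fMRI. Provides the steady-state inversion-recovery signal
    model with segment-specific excitation flip angles, gray/white-matter
    contrast-to-noise optimization over flip-angle pairs, lookup-table T1
    quantification with transmit-field (B1) binning, complex averaging of
    dual read-polarity volumes for EPI ghost and ripple cancellation,
    reverse-phase-encode displacement-field estimation with echo-spacing
    rescaling for distortion-matched or distortion-free synthesis, cortical
    depth profile extraction with landmark dip detection, and a digital brain
    phantom acquisition simulator that exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
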