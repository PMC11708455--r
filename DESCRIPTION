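Package: pwavekit
Title: P-Wave Parameter Measurement and Simulation for 12-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement pipeline for P-wave indices on digital 12-lead
    electrocardiograms: zero-phase band-pass and mains-notch filtering,
    R-peak detection, 20-beat P-wave template averaging, geometric
    (chord-distance) onset/peak/offset delineation with an annotation
    override hook, and computation of P-wave duration (PWD), P-wave
    voltage (PWV), P-wave dispersion (PWDisp) and the P-wave terminal
    force in lead V1 (PTFV1). Includes a calibrated synthetic 12-lead
    sinus-rhythm cohort generator with closed-form ground truth, a
    pre/post two-arm statistical layer (D'Agostino-Pearson normality
    gate, paired/unpaired t tests with rank-based fallbacks,
    intraobserver variability), and a study-report orchestrator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
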