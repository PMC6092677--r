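Package: tockysim
Title: Simulation and Analysis of Fluorescent Timer Reporter Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Timer-of-cell-kinetics-and-activity (Tocky) approach to
    flow cytometry of Fluorescent Timer reporters. Provides an exact closed-form
    simulator of the transcription -> blue chromophore -> red chromophore cascade
    under programmable transcription dynamics, including translation- and
    transcription-blockade calibration experiments; preprocessing of event tables
    (negative-control thresholding, Blue-Red normalisation) and the trigonometric
    transformation to Timer-Angle and Timer-Intensity; classification of events
    into the five transcription-dynamics loci (New, NPt, Persistent, PAt,
    Arrested) with per-sample summaries, boundary-corrected kernel density
    estimation of Timer-Angle, and marker profiling by locus; half-life
    estimation from fluorescence or qPCR Ct decay time courses; and
    quality-controlled group comparisons with the field's standard tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
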