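Package: assr40
Title: Simulation and Analysis of 40-Hz Auditory Steady-State Responses in MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation-driven pipeline for 40-Hz auditory steady-state
    response (ASSR) analysis in magnetoencephalography. Constructs
    amplitude-modulated tone stimuli with notch-filtered babble maskers,
    forward-simulates axial-gradiometer recordings of bilateral auditory
    cortex sources in a spherical conductor, screens head motion, removes
    ocular and cardiac artifacts by component regression, fits bilateral
    equivalent current dipoles to sub-averaged fields, projects source
    waveforms, computes the complex 40-Hz ASSR statistic with
    phase-randomization bootstrap significance and Hilbert-phase latency
    contrasts, and runs the cohort statistics: mixed-design ANOVA, linear
    models, logistic psychometric fits, and bootstrap mediation analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
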