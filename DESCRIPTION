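Package: mibci
Title: Motor-Imagery EEG Decoding, Closed-Loop Classification, and
    Pain-Diary Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for motor-imagery electroencephalography (EEG)
    brain-computer interfaces and the longitudinal pain outcomes of
    neurofeedback training. Simulates three-class motor-imagery sessions
    with contralateral mu/beta event-related desynchronization (ERD) and
    per-subject pain diaries; conditions raw EEG by zero-lag FIR band-pass
    filtering, trial epoching, sliding-window segmentation, and robust
    outlier-window rejection; calibrates a Common Spatial Patterns plus
    Linear Discriminant Analysis decoder with run-wise cross-validation and
    a competence gate; replays the decoder over continuous recordings at the
    closed-loop update rate; maps ERD/ERS with DPSS multitaper spectrograms;
    scores training exercises and session success; and analyses pain diaries
    with paroxysmal pain-volume statistics, period summary tables, and
    random-intercept linear mixed models. Reads and writes European Data
    Format (EDF+) recordings with annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
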