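Package: acuteqeeg
Title: Quantitative EEG Features and Sparse Integer Risk Scores for Acute
    Experimental Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-channel epidural EEG recorded around a
    controlled cortical impact (CCI) in rodents: event-locked epoching,
    zero-phase equiripple bandpass filtering (0.5-32 Hz), Welch power spectra
    binned at 0.5 Hz, baseline power normalisation, interhemispheric
    magnitude-squared coherence, spectral entropy, kurtosis and line length;
    bin-wise least-squares group statistics with LogWorth summaries and
    one-way ANOVA with Tukey HSD; and a sparse integer risk-score learner
    (bounded-coefficient logistic scoring via exact enumeration) with
    LogWorth-based dichotomisation and score-to-probability calibration.
    Includes a controllable synthetic two-channel EEG generator emulating the
    pre/post-injury signal structure of three rat strains, so the full
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
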