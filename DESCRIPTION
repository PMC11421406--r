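Package: vrteffort
Title: Automated Speech-Audiometry Response Analysis and Verbal Response
    Times as a Listening-Effort Proxy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for matrix sentence tests (50-word,
    five-slot speech material) in which the listener's spoken responses
    are scored and timed from word-level recognizer alignments.  Computes
    speech-recognition scores with rationalized arcsine (RAU)
    transformation, verbal response time (VRT) with its logarithmic
    transform, response speech rate (RSR), Rankit rank-normalized
    self-reported listening effort, within-participant z-standardization,
    intraclass correlation for examiner-vs-recognizer agreement, stepwise
    linear regression with Durbin-Watson and collinearity diagnostics, and
    per-participant correlations.  Includes a synthetic-cohort generator
    emulating a two-group (normal-hearing, hearing-impaired) design with
    stationary and fluctuating maskers at five SNRs relative to the
    individual speech-recognition threshold, and signal-processing tools
    for masker construction (pause shortening, spectral shaping,
    stationary-noise synthesis by superposition, section rearrangement,
    RMS normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
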