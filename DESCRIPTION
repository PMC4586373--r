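Package: ushrv
Title: Validity Analysis of Ultra-Short Time-Domain Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing how well SDNN and RMSSD computed from
    (ultra-)short NN-interval segments (10 s, 30 s, 120 s) agree with the
    same measures from a 240-300 s gold-standard resting recording.
    Includes a seeded synthetic NN-interval population generator with
    fast (respiratory) and slow (low-frequency plus drift) variability,
    artifact injection and the associated data-quality rules, segment
    selection, time-domain HRV metrics, agreement statistics (Pearson
    correlation, Bland-Altman 95% limits of agreement, Cohen's d,
    intraclass correlation with absolute agreement), and a bootstrap
    null simulation built on an interval-count-weighted variance
    decomposition and recombination of HRV values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
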