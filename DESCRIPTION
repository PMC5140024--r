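Package: pirsleep
Title: Home-Cage Activity and Sleep Phenotyping from Passive-Infrared Motion Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous, non-invasive phenotyping of activity and
    sleep in singly housed laboratory mice from passive-infrared (PIR) motion
    sensors. Reads per-epoch percent-activation traces with an environmental
    light channel, scores behavioural sleep as extended immobility (>= 40 s of
    zero detected movement), extracts sleep bouts, and quantifies circadian
    rhythmicity with the Sokolove-Bushell chi-squared periodogram, double-
    plotted actogram matrices, activity-onset detection and the nonparametric
    interdaily-stability and intradaily-variability statistics. Validates
    immobility-defined sleep against EEG/EMG hypnograms via Pearson
    correlation and Bland-Altman limits of agreement, split by light phase.
    Includes a semi-Markov behavioural-state simulator that generates PIR
    traces, matched hypnograms and light schedules with shared ground truth
    for end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
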