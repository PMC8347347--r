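Package: footsga
Title: Statistical Gait Analysis of Foot-Switch Basography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising human gait from bilateral foot-switch
    recordings (heel, first and fifth metatarsal head sensors). Implements
    anti-bounce run-length filtering of binary switch channels, encoding into
    the four-level gait-phase signal (heel contact, flat-foot contact,
    push-off, swing), automatic segmentation into gait cycles and
    classification by foot-floor contact sequence (typical HFPS versus
    atypical classes such as PFPS, PS, FPS and HFHFPS), spatio-temporal
    parameters (walking speed, cadence, double support, phase durations as
    percentage of the gait cycle), per-region atypical-cycle statistics over
    straight walking and U-turns, and a statistical battery: Lilliefors
    normality testing with Monte-Carlo p-values, two-group comparisons,
    two-way ANOVA with Tukey post-hoc, Hedges' g with small-sample
    correction, speed-normalised atypical-cycle rates, control-referenced
    subgroup selection, and seeded bootstrap confidence intervals for
    Pearson correlations with a clinical motor score. A synthetic cohort
    generator emulates five-minute back-and-forth walks over a nine-metre
    path so that every stage of the pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite,
    withr
Config/testthat/edition: 3
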