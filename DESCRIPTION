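Package: gazebias
Title: Affective Attentional Bias Analysis for Free-Viewing Eye-Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw 60 Hz gaze samples to age-related
    affective attentional bias results in a paired-image free-viewing task.
    Implements area-of-interest (AOI) dwell-time extraction with gap-tolerant
    sample binning and a minimum-bin-duration filter, trial- and
    participant-level quality-control exclusions, emotional bias scores,
    Emotion Regulation Questionnaire (ERQ) preference scoring, Fisher r-to-z
    comparison of independent correlations, noncentral-F power for
    within-between designs, and linear mixed-effects moderation models with
    Satterthwaite degrees of freedom, range-averaged marginal means, and age
    simple slopes at moderator levels. A semi-Markov gaze simulator generates
    synthetic cohorts with planted condition, age, emotion-regulation
    preference, and depression effects plus injectable acquisition artifacts,
    so every stage is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
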