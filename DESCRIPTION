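Package: cavidose
Title: Cavitation Dose and Blood-Brain Barrier Opening Analysis for Focused
    Ultrasound Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microbubble-mediated focused ultrasound
    blood-brain barrier disruption experiments. Implements per-burst spectral
    scoring of passive cavitation detection (PCD) hydrophone recordings
    (band-filtered Vrms at the subharmonic, fundamental, ultraharmonic and
    harmonic bands plus the broadband residual), treatment-level cavitation
    dose accumulation with baseline normalization, contrast-enhanced image
    quantification as the treated-to-contralateral hemisphere intensity fold,
    ordinal histology damage-score aggregation, and the small-sample group
    statistics used in such studies (exact Mann-Whitney by enumeration,
    one-way ANOVA with Dunnett many-to-one comparisons). A seeded
    synthetic-data module generates every input the pipeline consumes:
    microbubble diameter populations, burst-mode hydrophone recordings with
    controllable spectral content, matched low-pressure baselines, and
    hemisphere enhancement phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
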