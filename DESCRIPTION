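Package: neurocarousel
Title: Spectral, Phase-Amplitude Coupling and Place-Avoidance Analysis
    for Rodent LFP and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for rodent local field potential (LFP)
    recordings and open-field / rotating-arena behavior. Provides line-noise
    removal with zero-phase biquad notch cascades, band-pass filtering via
    second-order-section Butterworth designs, Welch power spectral density
    with baseline-percentage normalisation, time-frequency spectrograms,
    theta-gamma phase-amplitude coupling quantified by the phase-locking
    value (mean vector length of phase differences), rotating-arena active
    place avoidance metrics (sector entrances, shock schedules, room/arena
    reference-frame transforms) and open-field locomotion metrics, a
    normality-gated group-comparison layer (Shapiro-Wilk gate, one-way
    ANOVA with Tukey HSD, Kruskal-Wallis with Dunn post hoc), and a
    seed-deterministic synthetic-data generator producing theta-modulated
    gamma LFP with controllable coupling strength and confined random-walk
    trajectories, so that every stage of the pipeline is verifiable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
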