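Package: affectmusic
Title: Rule-Based Probabilistic Generation of Affective Classical Music
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates four-voice classical music whose musical surface is
    driven, bar by bar, by continuous valence and arousal inputs on the
    circumplex model of affect. Harmony is drawn from a valence-indexed
    probabilistic chord-progression matrix over a looping 8-bar theme;
    voice leading follows a dissimilarity-minimising chord-voicing rule,
    step-motion transition matrices and chord-tone melodies; tempo, note
    density and key velocity are mapped from arousal. Output is a standard
    MIDI file or a timestamped event stream. Also includes the listener
    validation pipeline (SAM rating normalisation, per-setting averaging,
    simple and multiple regression, musician-subgroup AIC comparison)
    together with a synthetic-rater simulator so the statistics are fully
    testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
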