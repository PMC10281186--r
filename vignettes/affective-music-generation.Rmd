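---
title: "Methods: affect-driven music generation and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: affect-driven music generation and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectmusic)
```

## The model

`affectmusic` composes four-voice music in a Western tonal idiom as a
semi-structured improvisation: a fixed 8-bar harmonic frame is re-realised
probabilistically, bar after bar, with every decision conditioned on the
current affect state — a point (valence, arousal) in the unit square of
the circumplex model of emotion. The per-bar update order is fixed:
chord, tenor voicing, rhythms, notes, velocity. Conditional on the seed,
trajectory and configuration the whole pipeline is deterministic, which
is what makes an otherwise stochastic music generator testable.

The musical mappings encode standard music-psychology findings: faster
tempo, higher note density and higher key velocity express arousal;
major mode, consonance and higher register express valence. Concretely:

| parameter | driven by | mapping | default constants |
|---|---|---|---|
| tempo | arousal | affine | 60–200 bpm |
| velocity range | arousal | affine bounds, fixed width 30 | [40, 70] → [85, 115] |
| velocity change cap | arousal | affine | 6–25 velocity units/bar |
| chord distribution | valence | 10-region × 8-bar matrix | shipped YAML |
| register bounds | valence | linear in semitones over 10 regions | [C1, C5] → [G3, C6] |
| roughness (alto density) | arousal | `max(0.3, 1 − a)` | floor 0.3 |
| soprano licks | arousal | 3 regions × 8 bars × 2 patterns | shipped YAML |
| alto step matrices | arousal | 2 regions × 4 states | shipped YAML |
| marimba doubling | valence | threshold | ≥ 0.8 |

All defaults live in `inst/extdata/default_config.yaml` and every section
can be replaced wholesale by a user file passed to `am_config()`.

## Region and boundary conventions

Regions are half-open, lower-inclusive intervals everywhere: valence
region k is [k/10, (k+1)/10) with valence 1 clamped into region 9, and
the arousal melody split is at 0.5 (0.5 belongs to the upper region). The
soprano rhythm regions are low (a < 0.4), moderate (0.4 ≤ a ≤ 0.75) and
high (a > 0.75); assigning a = 0.75 to *moderate* is our resolution of an
otherwise unclassified boundary point, consistent with the strict
inequality defining the high region. Affect inputs arriving from a
streaming callback are clamped into [0, 1] (tolerating sensor noise);
file and constant inputs are validated strictly and rejected when out of
range, so user errors fail loudly.

## Harmony

Each chord-matrix cell is a small categorical distribution: 1–5 candidate
chords with probabilities in [0.1, 0.8] summing to 1 (tolerance 1e-9). A
singleton cell with probability 1 is accepted as a degenerate
distribution. Bar 8 candidates must all be cadential, closing every theme
iteration. The published description of the system constrains the matrix
but does not publish it, so the shipped matrix is authored data: regions
0–4 are composed in C natural minor and 5–9 in C major, and each cell
mixes two consonant candidates with one dissonant candidate whose
probability decreases from 0.8 to 0.1 as valence rises.

To make the intended dissonance gradient checkable we define a dissonance
score: the count of tone pairs at interval class 1 (minor second/major
seventh) or 6 (tritone), plus 1 for diminished or augmented quality. The
probability-weighted expected score of each cell must be nonincreasing
across valence regions for every theme bar; `load_chord_matrix()` enforces
this (and all other invariants) on any user-supplied matrix. The score is
a validation oracle only — generation never consults it.

The chord vocabulary is limited to eight triad/seventh qualities (major,
minor, diminished, augmented, dominant 7th, minor 7th, major 7th,
half-diminished 7th), which covers the named sources of dissonance
without inventing extended harmony. Key modulation between theme
iterations is out of scope.

## Voice leading

**Tenor.** The tenor plays a full chord voicing in a middle-register
window, inset from the valence region's bounds by an octave at the bottom
and a fourth at the top (both unquantified in prose descriptions of such
systems; the inset is configurable through the register table). All
voicings that realize each chord tone's pitch class exactly once inside
the window are enumerated, and the one minimising the all-pairs
dissimilarity Σᵢ Σⱼ |Nᵢ − N′ⱼ| against the previous voicing is chosen.
The double sum is implemented exactly as written — it is not a
matched-pair distance and is nonzero even between identical multi-note
sets; since it is only ever used as a ranking criterion over candidates
against a fixed previous voicing, the constant inflation is harmless.
Ties are broken by lowest bass pitch, then lexicographic order, making
the argmin unique and reproducible. The first bar draws a random
candidate.

**Alto.** A monophonic step-motion line: states −1/+1 move one diatonic
step, 0 repeats, CT jumps to a random chord tone. The governing scale is
taken from the valence region's mode (natural minor below region 5, major
from region 5), tonic C by default. When the soprano melody changes pitch
the alto's state is constrained to {−1, +1} (row renormalised), which is
what enforces the "move by diatonic step with the melody" rule; "the
melody changed" is evaluated per alto onset against the most recent
soprano onset at or before it, and only once per new soprano note. Steps
that would leave the register window are reflected rather than clamped,
avoiding pitch pile-up at the boundary; the alto state carries over
across bar boundaries. When a valence jump moves the register window away
from the carried pitch, the line is re-seated on the nearest chord tone
inside the new window (recorded as a CT move) — the step rule cannot
bridge a register shift of up to two octaves within one bar.

The shipped transition matrices are authored data: the low-arousal matrix
favours repeats and chord-tone jumps; the high-arousal matrix boosts
−1/+1 self-transitions so melodies tend toward scale runs. Parallel
fifths are not explicitly prohibited (the system's probabilistic nature
makes them rare); the test suite checks a soft bound — under 10% of
consecutive-bar transitions, a threshold that is ours — over a 1,000-bar
seeded run.

**Soprano and bass.** The soprano is a uniform random chord-tone sequence
realized in the top two octaves of the register bounds, over licks drawn
equiprobably from the bank; note durations fill to the next onset. The
bass plays the chord root, whole-bar, fixed in the C3 octave (MIDI
48–59). MIDI numbering uses the middle C = C4 = 60 convention throughout.

## Rhythm

Bars are 4/4 on an eighth-note grid (8 subdivisions), inferred from the
"eight equal notes at roughness 0" description. The alto onset count is
`round(8·(1 − roughness))`, clamped to at least 1 — our operationalization
of density-as-inverse-roughness, linear between the stated endpoints —
with positions drawn without replacement but always including the
downbeat, so no bar sounds like a dropout. The shipped lick bank's mean
onset count rises across the low/moderate/high regions (about 1.4, 3.3
and 6.4 onsets per bar), a documented design property of the bank rather
than a law of the model.

## MIDI output

Scores serialise as format-1 standard MIDI: a conductor track holding a
tempo meta-event at every bar where tempo changes, plus one track per
instrument (strings 48, piano 0, clarinet 71, marimba 12 as General-MIDI
programs on distinct channels; both inner voices share the piano). The
resolution of 480 ticks per quarter makes the eighth-note grid exact
(240 ticks), and all timing is integer arithmetic, so files are
byte-stable across platforms. The same event sequence backs the file
writer, the reader and the real-time streaming contract
(`stream_events()`), and round-trip identity is tested. Audio rendering
and DAW integration are out of scope; the marimba doubling threshold and
the 16-bar "fast tempo" stimulus cutoff (120 bpm, the tempo midpoint,
since the cutoff is unpublished) are configurable.

## Stimulus batches

`generate_stimuli()` reproduces the validation design: 13 affect points
(corners, quadrant middles, edge midpoints, centre) × 3 instances = 39
excerpts, 16 bars at fast tempo and 8 otherwise, each instance from the
derived seed `seed + (point − 1)·1000 + instance` so any single file can
be regenerated in isolation.

## The synthetic rater simulator

Human ratings for this kind of system are not redistributable, so the
statistics pipeline ships with its own generative stand-in.
`simulate_ratings()` draws, for each of 26 raters × 39 stimuli, latent
perceived valence `slope_v·V + crossover·A + ε` and latent perceived
arousal `slope_a·A + ε` with ε ~ N(0, noise_sd), then affine-maps latents
to the 9-point SAM scale (`1 + 8x`), rounds, and clips to 1–9. Defaults:
`slope_v = slope_a = 1`, `crossover_a_on_v = 0.15`, `noise_sd = 0.1`
(normalized units), musician fraction 12/26. The crossover is
deliberately asymmetric — intended arousal colours perceived valence but
not vice versa — because that is the qualitative pattern such listener
studies report; 0.15 is our choice of a moderate, detectable effect, and
0.1 is a plausible rating-noise scale for a 9-point instrument. These
defaults are the simulator's study conditions, not tuning knobs.

What the simulator does *not* emulate: inter-rater heterogeneity
(systematic rater biases or scale-use differences), central-tendency and
end-of-scale response styles, order effects, any genuine difference
between musician and non-musician raters, and any dependence of ratings
on the actual audio. Consequently, passing statistical-recovery tests
shows the *pipeline* is correct (normalisation, averaging, regressions,
AIC bookkeeping, power to detect the crossover at the shipped effect
size), not that the generated music conveys emotion to humans — the
human-study headline statistics are explicitly out of reach at desk
scale and are not asserted anywhere in the package.

One auditability quirk: the printed normalisation formula in this
literature divides by (max − min) without subtracting the minimum, which
cannot produce the stated 0–1 range. The default `corrected` mode uses
`(rated − 1)/8`; the literal `as_printed` form (range 0.125–1.125) is
retained behind a flag for audit.

## Statistical conventions

Regressions are ordinary least squares via `lm()`. The simple regression
uses setting-level means (5 levels per dimension); the crossover multiple
regression uses per-point means (13 rows) by default, with a
record-level alternative behind a flag, since the averaging unit is
ambiguous in figure-level analyses of this kind. Per-predictor F
statistics are squared t statistics (partial F, 1 numerator df). AIC is
the Gaussian-likelihood `stats::AIC()` convention (parameters = intercept
+ slopes + residual variance). A constant response is reported as
R² = 0, F = 0, p = 1 rather than the numerically unstable ratio `lm`
produces in that degenerate case.

## Problem sizes and tolerances in the test suite

Chosen to make sampling checks decisive while keeping the default run
fast: chi-square goodness-of-fit oracles use 10,000 draws at α = 0.01;
the voicing argmin is checked against an independent subset-enumeration
oracle on 200 random chord pairs; voice-leading properties use a single
1,000-bar seeded run; slope recovery averages 100 simulated studies and
the crossover power / type-I calibration uses 1,000 replicates of the
full 26-rater design. Probability sums and monotonicity checks use
tolerance 1e-9 or tighter; musical counts are exact.

## Known limitations

* The shipped chord matrix, licks, step matrices and per-region register
  interpolation are authored defaults satisfying the documented
  constraints — they are not recovered from any published artefact, and
  substituting your own configuration changes the musical result.
* One key (tonic C) per run; no modulation, swing, tuplets, articulation
  or sub-bar parameter interpolation (parameters update per bar only).
* The MIDI reader supports the subset of the format the writer emits
  (plus running status); it is a round-trip verifier, not a general
  MIDI parser.
* Voicing enumeration realizes each chord tone exactly once (no
  doublings or omissions), which is what makes the argmin well-defined
  and cheap.
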