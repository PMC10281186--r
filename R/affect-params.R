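#' Tempo from arousal
#'
#' Tempo is an affine function of arousal: 60 bpm at arousal 0 rising to
#' 200 bpm at arousal 1. Valence has no effect on tempo.
#'
#' @param state An [affect_state()].
#' @param min_bpm,max_bpm Tempo endpoints in beats per minute.
#' @return Tempo in bpm.
#' @examples
#' tempo_from_arousal(affect_state(0.5, 0))    # 60
#' tempo_from_arousal(affect_state(0.5, 1))    # 200
#' tempo_from_arousal(affect_state(0.5, 0.5))  # 130
#' @export
tempo_from_arousal <- function(state, min_bpm = 60, max_bpm = 200) {
  state <- as_affect_state(state)
  min_bpm + state$arousal * (max_bpm - min_bpm)
}

#' Permissible MIDI velocity range from arousal
#'
#' The range of permissible key velocities is \[40, 70\] at arousal 0; both
#' bounds rise linearly with arousal, by 45 velocity units over the full
#' arousal range, reaching \[85, 115\] at arousal 1. The width is therefore
#' constant at 30. Higher velocity yields brighter, harder timbres.
#'
#' @param state An [affect_state()].
#' @return Named numeric vector `c(low, high)` (unrounded).
#' @examples
#' velocity_range(affect_state(0, 0))  # c(40, 70)
#' velocity_range(affect_state(0, 1))  # c(85, 115)
#' @export
velocity_range <- function(state) {
  state <- as_affect_state(state)
  c(low = 40 + state$arousal * 45, high = 70 + state$arousal * 45)
}

#' Sample the velocity for one bar
#'
#' One velocity is drawn per bar and applied to every note in that bar; there
#' are no velocity changes within a bar. The draw is uniform over the
#' arousal-dependent permissible range ([velocity_range()]), additionally
#' limited so that the change from the previous bar's velocity does not
#' exceed an arousal-dependent cap: the allowed deviation is
#' `delta_min + arousal * (delta_max - delta_min)`, smaller at low arousal
#' where abrupt loudness changes would sound unnatural. If the capped window
#' does not intersect the permissible range, the draw is clamped to the
#' nearest endpoint of the permissible range.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param state An [affect_state()].
#' @param previous_velocity Velocity of the previous bar, or `NULL` for the
#'   first bar.
#' @param delta Numeric `c(min, max)`: velocity-change cap at arousal 0 and 1.
#' @return Integer MIDI velocity in 0--127.
#' @export
sample_bar_velocity <- function(state, previous_velocity = NULL,
                                delta = c(min = 6, max = 25)) {
  state <- as_affect_state(state)
  rng <- velocity_range(state)
  if (is.null(previous_velocity)) {
    v <- stats::runif(1, rng[["low"]], rng[["high"]])
  } else {
    cap <- delta[[1]] + state$arousal * (delta[[2]] - delta[[1]])
    lo <- max(rng[["low"]], previous_velocity - cap)
    hi <- min(rng[["high"]], previous_velocity + cap)
    v <- if (lo > hi) {
      # capped window misses the permissible range entirely: snap to the
      # nearest permissible endpoint
      if (previous_velocity < rng[["low"]]) rng[["low"]] else rng[["high"]]
    } else {
      stats::runif(1, lo, hi)
    }
  }
  as.integer(min(max(round(v), 0), 127))
}

#' Valence region index
#'
#' The valence range is divided into 10 equal regions (indices 0--9), each
#' with its own probabilistic chord progression and register bounds. Regions
#' are half-open lower-inclusive intervals \[k/10, (k+1)/10), with valence 1
#' clamped into region 9.
#'
#' @param state An [affect_state()].
#' @return Integer region index in 0--9.
#' @export
valence_region <- function(state) {
  state <- as_affect_state(state)
  min(as.integer(floor(state$valence * 10)), 9L)
}

#' Register bounds for the current valence region
#'
#' Both the lower and upper bound of the permissible pitch range rise with
#' valence: from \[C1, C5\] (MIDI 24--72) in the lowest valence region to
#' \[G3, C6\] (MIDI 55--84) in the highest, interpolated linearly in
#' semitones across the 10 regions and rounded to integers. These bounds
#' govern the soprano, alto and tenor voices; the bass register is fixed at
#' the C3 octave (see [bass_note()]). MIDI numbering follows the middle
#' C = C4 = 60 convention.
#'
#' @param state An [affect_state()].
#' @param table Optional 10 x 2 integer matrix of per-region `(low, high)`
#'   bounds overriding the interpolated defaults (rows are regions 0--9).
#' @return Named integer vector `c(low, high)`.
#' @export
register_bounds <- function(state, table = NULL) {
  region <- valence_region(state)
  if (is.null(table)) table <- default_register_table()
  stopifnot(is.matrix(table), nrow(table) == 10L, ncol(table) == 2L)
  b <- table[region + 1L, ]
  c(low = as.integer(b[[1]]), high = as.integer(b[[2]]))
}

default_register_table <- function() {
  k <- 0:9
  cbind(low = as.integer(round(24 + k * (55 - 24) / 9)),
        high = as.integer(round(72 + k * (84 - 72) / 9)))
}

#' Arousal region for soprano rhythm licks
#'
#' The arousal range is divided into three regions governing which set of
#' soprano rhythm patterns is drawn from: low (arousal < 0.4), moderate
#' (0.4 <= arousal <= 0.75) and high (arousal > 0.75).
#'
#' @param state An [affect_state()].
#' @return One of `"low"`, `"moderate"`, `"high"`.
#' @export
arousal_rhythm_region <- function(state) {
  state <- as_affect_state(state)
  a <- state$arousal
  if (a < 0.4) "low" else if (a <= 0.75) "moderate" else "high"
}

#' Arousal region for the alto melody transition matrix
#'
#' The arousal range is split into two equal halves, each with its own
#' step-motion transition matrix: region 0 for arousal < 0.5, region 1
#' otherwise.
#'
#' @param state An [affect_state()].
#' @return Integer 0 or 1.
#' @export
arousal_melody_region <- function(state) {
  state <- as_affect_state(state)
  if (state$arousal < 0.5) 0L else 1L
}

#' Rhythmic roughness from arousal
#'
#' Roughness (irregularity of note durations, proxied inversely by note
#' density) decreases as arousal increases: `max(floor, 1 - arousal)`. The
#' floor (default 0.3) prevents overly dense bars at high arousal, where
#' tempo is already fast.
#'
#' @param state An [affect_state()].
#' @param floor Lowest permitted roughness.
#' @return Roughness in `[floor, 1]`.
#' @export
roughness_from_arousal <- function(state, floor = 0.3) {
  state <- as_affect_state(state)
  max(floor, 1 - state$arousal)
}
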