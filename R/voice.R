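#' Dissimilarity between two chord voicings
#'
#' The dissimilarity between notesets N and N' is the double sum of
#' `|N_i - N'_j|` over *all* ordered pairs of pitches, one from each set --
#' not a matched-pair distance. It is symmetric in its arguments and is the
#' quantity minimised when choosing each new tenor voicing, emulating the
#' pianist's habit of voicing a new chord as close to the previous one as
#' possible.
#'
#' @param n,n_prime Numeric vectors of MIDI pitches (non-empty).
#' @return Nonnegative total of all pairwise absolute pitch differences.
#' @examples
#' voicing_dissimilarity(60, 60)  # 0
#' voicing_dissimilarity(60, 62)  # 2
#' @export
voicing_dissimilarity <- function(n, n_prime) {
  if (length(n) == 0L || length(n_prime) == 0L)
    stop("voicings must be non-empty", call. = FALSE)
  sum(abs(outer(as.numeric(n), as.numeric(n_prime), "-")))
}

# The tenor plays full voicings in the middle register: a window inset from
# the valence-region bounds by an octave at the bottom and a fourth at the top.
tenor_window <- function(bounds) {
  c(low = bounds[["low"]] + 12L, high = bounds[["high"]] - 5L)
}

alto_window <- function(bounds) {
  c(low = bounds[["low"]] + 12L, high = bounds[["high"]])
}

# The soprano melody sits in the top two octaves of the permissible range.
soprano_window <- function(bounds) {
  c(low = max(bounds[["low"]], bounds[["high"]] - 24L), high = bounds[["high"]])
}

#' Enumerate all voicings of a chord inside a pitch window
#'
#' A voicing realizes each chord tone's pitch class exactly once, at some
#' octave inside the window; pitches are reported in ascending order.
#'
#' @param chord An [chord()] object.
#' @param window Numeric `c(low, high)` MIDI pitch window (inclusive).
#' @return List of ascending integer pitch vectors, in lexicographic order.
#' @export
enumerate_voicings <- function(chord, window) {
  stopifnot(inherits(chord, "am_chord"))
  lo <- as.integer(window[[1]]); hi <- as.integer(window[[2]])
  if (hi < lo) return(list())
  per_pc <- lapply(chord$tones, function(pc) {
    p <- seq.int(lo, hi)
    p[p %% 12L == pc]
  })
  if (any(vapply(per_pc, length, 0L) == 0L)) return(list())
  grid <- expand.grid(per_pc, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    sort(as.integer(unlist(grid[i, ], use.names = FALSE))))
  # canonical (lexicographic) order: lowest bass pitch first, then upwards
  ord <- do.call(order, as.data.frame(do.call(rbind, out)))
  out[ord]
}

#' Choose the tenor voicing for a new chord
#'
#' Enumerates every voicing of the chord within the tenor's middle-register
#' window and returns the one minimising [voicing_dissimilarity()] against
#' the previous voicing. For the first bar (no previous voicing) a random
#' candidate is drawn. Ties are broken by lowest bass pitch, then
#' lexicographic order of the remaining pitches.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param chord An [chord()] object.
#' @param previous Previous bar's voicing (ascending MIDI pitches), or
#'   `NULL` for the first bar.
#' @param bounds Register bounds `c(low, high)` for the current valence
#'   region (see [register_bounds()]); the tenor window is derived from them.
#' @return Ascending integer vector of MIDI pitches.
#' @export
choose_tenor_voicing <- function(chord, previous = NULL, bounds) {
  win <- tenor_window(bounds)
  cands <- enumerate_voicings(chord, win)
  if (length(cands) == 0L)
    stop(sprintf("no voicing of chord '%s' fits the tenor window [%d, %d]",
                 chord$label, win[["low"]], win[["high"]]), call. = FALSE)
  if (is.null(previous)) return(cands[[sample.int(length(cands), 1L)]])
  d <- vapply(cands, voicing_dissimilarity, 0, n_prime = previous)
  cands[[which.min(d)]]  # candidates are in canonical order, so the first
                         # minimum is the tie-break winner
}

# ---- scale context ----------------------------------------------------------

MAJOR_SCALE <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
NATURAL_MINOR_SCALE <- c(0L, 2L, 3L, 5L, 7L, 8L, 10L)

#' Diatonic scale governing a valence region
#'
#' The lower five valence regions use the natural minor scale on the tonic,
#' the upper five the major scale, matching the modal plan of the shipped
#' chord matrix.
#'
#' @param region Valence region 0--9.
#' @param tonic Tonic pitch class (default 0 = C).
#' @return Integer vector of 7 scale pitch classes.
#' @export
scale_for_region <- function(region, tonic = 0L) {
  region <- as.integer(region)
  stopifnot(region >= 0L, region <= 9L)
  base <- if (region < 5L) NATURAL_MINOR_SCALE else MAJOR_SCALE
  sort((tonic + base) %% 12L)
}

#' Move one diatonic step up or down
#'
#' Returns the nearest pitch above (direction +1) or below (direction -1)
#' the current pitch whose pitch class belongs to the scale. Defined for any
#' starting pitch, in or out of the scale.
#'
#' @param pitch MIDI pitch.
#' @param direction `+1` (up) or `-1` (down).
#' @param scale_pcs Integer vector of scale pitch classes.
#' @return MIDI pitch one diatonic step away.
#' @export
diatonic_step <- function(pitch, direction, scale_pcs) {
  stopifnot(direction %in% c(-1L, 1L))
  p <- as.integer(pitch) + as.integer(direction)
  while (!(p %% 12L) %in% scale_pcs) p <- p + as.integer(direction)
  p
}

#' Next alto pitch from the step-motion transition matrix
#'
#' Samples a motion state from the matrix row of the previous state: `-1`
#' or `+1` move one diatonic step down/up, `0` repeats the pitch, `CT`
#' jumps to a random chord-tone realization inside the alto window. When
#' the soprano melody has just changed pitch (`melody_changed`), the state
#' is constrained to a step (`-1`/`+1`, row renormalised) so the alto moves
#' by diatonic step alongside it. A step that would leave the register
#' bounds is reflected (taken in the opposite direction) rather than
#' clamped, avoiding pitch pile-up at the boundary.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param current_pitch Current alto MIDI pitch.
#' @param prev_state Previous motion state (`"-1"`, `"+1"`, `"0"`, `"CT"`).
#' @param melody_changed Did the governing soprano pitch just change?
#' @param chord Current [chord()] (for `CT` jumps).
#' @param matrix 4 x 4 row-stochastic transition matrix with the states as
#'   dimnames (see [load_step_matrices()]).
#' @param scale_pcs Scale pitch classes (see [scale_for_region()]).
#' @param bounds Register bounds `c(low, high)`; the alto window is derived
#'   from them.
#' @return List with fields `pitch` (MIDI integer) and `state` (the motion
#'   state realised, after any boundary reflection).
#' @export
next_alto_note <- function(current_pitch, prev_state, melody_changed, chord,
                           matrix, scale_pcs, bounds) {
  win <- alto_window(bounds)
  row <- matrix[prev_state, ]
  if (isTRUE(melody_changed)) {
    row <- row[c("-1", "+1")]
    if (sum(row) <= 0) row <- c("-1" = 0.5, "+1" = 0.5)
    row <- row / sum(row)
  }
  st <- sample(names(row), 1L, prob = row)
  if (st %in% c("-1", "+1")) {
    dir <- if (st == "-1") -1L else 1L
    p <- diatonic_step(current_pitch, dir, scale_pcs)
    if (p < win[["low"]] || p > win[["high"]]) {
      dir <- -dir
      st <- if (dir < 0L) "-1" else "+1"
      p <- diatonic_step(current_pitch, dir, scale_pcs)
    }
    return(list(pitch = p, state = st))
  }
  if (st == "0") return(list(pitch = as.integer(current_pitch), state = "0"))
  # CT: jump to a random chord-tone realization inside the window
  reals <- chord_tone_pitches(chord, win)
  if (length(reals) == 0L)
    return(list(pitch = as.integer(current_pitch), state = "0"))
  list(pitch = reals[[sample.int(length(reals), 1L)]], state = "CT")
}

chord_tone_pitches <- function(chord, window) {
  p <- seq.int(as.integer(window[[1]]), as.integer(window[[2]]))
  p[(p %% 12L) %in% chord$tones]
}

#' Soprano melody notes for one bar
#'
#' The principal melody is a random sequence of chord tones: one note per
#' onset of the rhythm lick, each pitch drawn uniformly from the chord-tone
#' realizations inside the soprano portion of the register bounds. Each
#' note's duration fills to the next onset (or the bar end).
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param chord An [chord()] object.
#' @param lick Integer vector of 8 binary onset indicators.
#' @param bounds Register bounds `c(low, high)` for the current valence
#'   region.
#' @return Data frame of note events with columns `voice`, `pitch`, `onset`,
#'   `duration` (velocity is assigned per bar by the generator).
#' @export
soprano_notes <- function(chord, lick, bounds) {
  if (sum(lick) < 1L) stop("lick has no onsets", call. = FALSE)
  win <- soprano_window(bounds)
  reals <- chord_tone_pitches(chord, win)
  if (length(reals) == 0L)
    stop(sprintf("no chord-tone realization of '%s' inside the soprano window [%d, %d]",
                 chord$label, win[["low"]], win[["high"]]), call. = FALSE)
  on <- lick_onsets(lick)
  dur <- lick_durations(lick)
  pitch <- reals[sample.int(length(reals), length(on), replace = TRUE)]
  data.frame(voice = "soprano", pitch = as.integer(pitch),
             onset = as.integer(on), duration = as.integer(dur),
             stringsAsFactors = FALSE)
}

#' Bass note for one bar
#'
#' The bass (string section) always plays the root of the current chord as
#' a single whole-bar note, in the fixed register octave anchored at C3
#' (MIDI 48--59).
#'
#' @param chord An [chord()] object.
#' @return One-row data frame of note events (`voice`, `pitch`, `onset`,
#'   `duration`).
#' @export
bass_note <- function(chord) {
  stopifnot(inherits(chord, "am_chord"))
  data.frame(voice = "bass", pitch = 48L + chord$root, onset = 0L,
             duration = SUBDIVISIONS, stringsAsFactors = FALSE)
}
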