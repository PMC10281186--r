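#' Position within the looping 8-bar theme
#'
#' The music loops through an 8-bar theme with a fixed chord function per
#' bar; the theme position of absolute bar `b` (1-based) is its bar within
#' the theme (1--8) plus the completed-iteration count.
#'
#' @param bar Absolute bar number, 1-based.
#' @return List with integer fields `bar_in_theme` (1--8) and `iteration`
#'   (0-based count of completed theme cycles).
#' @examples
#' theme_position(1)   # bar 1, iteration 0
#' theme_position(9)   # bar 1, iteration 1
#' theme_position(24)  # bar 8, iteration 2
#' @export
theme_position <- function(bar) {
  bar <- as.integer(bar)
  stopifnot(length(bar) == 1L, bar >= 1L)
  list(bar_in_theme = ((bar - 1L) %% 8L) + 1L,
       iteration = (bar - 1L) %/% 8L)
}

#' Sample one chord from the chord matrix
#'
#' Draws a chord from the categorical distribution stored in the matrix
#' cell addressed by the current valence region and the bar's position in
#' the theme. Arousal has no influence on the chord drawn.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param matrix An `am_chord_matrix` (see [load_chord_matrix()]).
#' @param bar_in_theme Theme bar 1--8, or a list as returned by
#'   [theme_position()].
#' @param state An [affect_state()]; only its valence is consulted.
#' @return An [chord()] object.
#' @export
sample_chord <- function(matrix, bar_in_theme, state) {
  stopifnot(inherits(matrix, "am_chord_matrix"))
  if (is.list(bar_in_theme)) bar_in_theme <- bar_in_theme$bar_in_theme
  bar_in_theme <- as.integer(bar_in_theme)
  stopifnot(bar_in_theme >= 1L, bar_in_theme <= 8L)
  region <- valence_region(state)
  cell <- matrix$cells[[region + 1L]][[bar_in_theme]]
  i <- if (length(cell$prob) == 1L) 1L else {
    sample.int(length(cell$prob), 1L, prob = cell$prob)
  }
  cell$chords[[i]]
}
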