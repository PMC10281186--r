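chord_quality_intervals <- list(
  major            = c(0L, 4L, 7L),
  minor            = c(0L, 3L, 7L),
  diminished       = c(0L, 3L, 6L),
  augmented        = c(0L, 4L, 8L),
  dominant7        = c(0L, 4L, 7L, 10L),
  minor7           = c(0L, 3L, 7L, 10L),
  major7           = c(0L, 4L, 7L, 11L),
  half_diminished7 = c(0L, 3L, 6L, 10L)
)

#' Construct a chord
#'
#' A chord is a root pitch class plus a quality from a fixed vocabulary of
#' eight triad/seventh qualities; its tones are the pitch classes derived
#' from root and quality, root first.
#'
#' @param root Root pitch class, integer 0--11 (0 = C).
#' @param quality One of `"major"`, `"minor"`, `"diminished"`, `"augmented"`,
#'   `"dominant7"`, `"minor7"`, `"major7"`, `"half_diminished7"`.
#' @param label Human-readable roman-numeral/function label; defaults to
#'   `"<root>:<quality>"`.
#' @param cadential Logical: does this chord carry a cadential function
#'   (used to validate bar 8 of the theme)?
#' @return An object of class `am_chord` with fields `root`, `quality`,
#'   `tones`, `label`, `cadential`.
#' @examples
#' chord(0, "major", "I")
#' chord(7, "dominant7", "V7", cadential = TRUE)
#' @export
chord <- function(root, quality, label = NULL, cadential = FALSE) {
  root <- as.integer(root)
  stopifnot(length(root) == 1L, root >= 0L, root <= 11L)
  quality <- match.arg(quality, names(chord_quality_intervals))
  tones <- (root + chord_quality_intervals[[quality]]) %% 12L
  if (is.null(label)) label <- paste0(root, ":", quality)
  structure(list(root = root, quality = quality, tones = tones,
                 label = label, cadential = isTRUE(cadential)),
            class = "am_chord")
}

#' @export
print.am_chord <- function(x, ...) {
  cat(sprintf("<chord> %s (root pc %d, %s; tones %s)\n",
              x$label, x$root, x$quality, paste(x$tones, collapse = " ")))
  invisible(x)
}

#' Dissonance score of a chord
#'
#' Counts, over all unordered pairs of chord tones, the pairs whose interval
#' class is a minor second / major seventh (ic 1) or a tritone (ic 6), and
#' adds 1 when the chord quality is diminished or augmented. This is a
#' validation oracle for the chord matrix's dissonance gradient (dissonance
#' should fall as valence rises); it is never consulted during generation.
#'
#' @param x An [chord()] object.
#' @return Nonnegative integer score.
#' @examples
#' dissonance_score(chord(0, "major"))       # 0
#' dissonance_score(chord(11, "diminished")) # 2 (tritone pair + quality)
#' @export
dissonance_score <- function(x) {
  stopifnot(inherits(x, "am_chord"))
  tones <- x$tones
  score <- 0L
  n <- length(tones)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- abs(tones[[i]] - tones[[j]]) %% 12L
      ic <- min(d, 12L - d)
      if (ic == 1L || ic == 6L) score <- score + 1L
    }
  }
  if (x$quality %in% c("diminished", "augmented")) score <- score + 1L
  score
}
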