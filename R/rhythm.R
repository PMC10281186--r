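# Bars are in 4/4 on an eighth-note grid: 8 subdivisions per bar.
SUBDIVISIONS <- 8L

#' Sample a soprano rhythm lick
#'
#' For the current arousal rhythm region and theme bar, the lick bank holds
#' two stored onset patterns; one is drawn with equal probability.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param bank An `am_lick_bank` (see [load_lick_bank()]).
#' @param region `"low"`, `"moderate"` or `"high"`
#'   (see [arousal_rhythm_region()]).
#' @param theme_bar Theme bar 1--8.
#' @return Integer vector of 8 binary onset indicators.
#' @export
sample_soprano_lick <- function(bank, region, theme_bar) {
  stopifnot(inherits(bank, "am_lick_bank"))
  region <- match.arg(region, c("low", "moderate", "high"))
  theme_bar <- as.integer(theme_bar)
  stopifnot(theme_bar >= 1L, theme_bar <= 8L)
  cell <- bank$bank[[region]][[theme_bar]]
  cell[[sample.int(2L, 1L)]]
}

#' Alto onset pattern from roughness
#'
#' Note density is the inverse proxy for rhythmic roughness: the number of
#' alto onsets in the bar is `round(8 * (1 - roughness))`, clamped to at
#' least 1. At (hypothetical) roughness 0 the bar holds eight equal notes.
#' Onset positions are drawn uniformly without replacement from the 8
#' subdivisions, always including the downbeat (subdivision 0) so the
#' harmony is anchored.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param roughness Roughness value (the generator supplies values in
#'   `[0.3, 1]`; see [roughness_from_arousal()]).
#' @return Integer vector of 8 binary onset indicators.
#' @export
alto_onsets <- function(roughness) {
  stopifnot(is.numeric(roughness), length(roughness) == 1L,
            roughness >= 0, roughness <= 1)
  n <- max(1L, as.integer(round(SUBDIVISIONS * (1 - roughness))))
  pos <- 0L
  if (n > 1L) pos <- c(pos, sample(seq_len(SUBDIVISIONS - 1L), n - 1L))
  lick <- integer(SUBDIVISIONS)
  lick[pos + 1L] <- 1L
  lick
}

#' Fixed rhythm pattern for bass and tenor
#'
#' The bass (string section) and tenor (piano chord voicing) voices play a
#' fixed pattern: a single onset on the first beat of each bar, sustained
#' for the whole bar.
#'
#' @param voice `"bass"` or `"tenor"`.
#' @return Integer vector of 8 binary onset indicators (onset at
#'   subdivision 0 only).
#' @export
fixed_pattern <- function(voice) {
  if (!voice %in% c("bass", "tenor"))
    stop("fixed_pattern applies to the bass and tenor voices only, got '",
         voice, "'", call. = FALSE)
  c(1L, integer(SUBDIVISIONS - 1L))
}

# onset indices (0-based) and fill-to-next-onset durations for a lick
lick_onsets <- function(lick) which(lick == 1L) - 1L

lick_durations <- function(lick) {
  on <- lick_onsets(lick)
  diff(c(on, SUBDIVISIONS))
}
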