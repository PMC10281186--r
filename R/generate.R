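#' Generate affective music from an affect trajectory
#'
#' Runs the full per-bar pipeline: the current affect state selects the
#' valence region and arousal regions; a chord is sampled from the
#' valence-indexed matrix at the current theme bar; the tenor voicing is
#' chosen by dissimilarity minimisation against the previous bar; rhythm
#' patterns are drawn (stored licks for the soprano, roughness-driven onset
#' density for the alto, fixed whole-bar onsets for bass and tenor); note
#' events are realized (bass root, tenor voicing, step-motion alto,
#' chord-tone soprano, marimba doubling of the soprano at valence >= 0.8);
#' finally one velocity is sampled for the bar and applied to every note.
#' The result is fully deterministic given `(trajectory, n_bars, seed,
#' config)`.
#'
#' @param trajectory Anything accepted by [affect_trajectory()].
#' @param n_bars Number of bars to generate (>= 1).
#' @param seed Integer seed for the generation RNG stream, or `NULL` to use
#'   the current RNG state.
#' @param config An [am_config()] object, a path to a config file, or
#'   `NULL` for the shipped defaults.
#' @return An object of class `affect_score`: a list with `bars` (one bar
#'   plan per bar: theme position, affect state, tempo, chord, bar velocity,
#'   note-event data frame and bookkeeping fields), plus `n_bars`, `seed`
#'   and `ticks_per_quarter`.
#' @examples
#' score <- generate(c(0.9, 0.7), n_bars = 8, seed = 1)
#' summary(score)
#' @export
generate <- function(trajectory, n_bars, seed = NULL, config = NULL) {
  config <- am_config(config)
  trajectory <- affect_trajectory(trajectory)
  n_bars <- as.integer(n_bars)
  stopifnot(n_bars >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))

  bars <- vector("list", n_bars)
  prev_voicing <- NULL
  prev_velocity <- NULL
  alto_pitch <- NULL
  alto_state <- "CT"
  # running soprano melody history: global onset (in subdivisions) and pitch
  sop_hist_tick <- integer()
  sop_hist_pitch <- integer()
  last_gov <- 0L

  for (b in seq_len(n_bars)) {
    pos <- theme_position(b)
    state <- state_at(trajectory, b)
    region <- valence_region(state)
    bounds <- register_bounds(state, table = config$register_table)
    scale_pcs <- scale_for_region(region, config$tonic)
    tempo <- tempo_from_arousal(state, config$tempo[["min_bpm"]],
                                config$tempo[["max_bpm"]])
    bar_plan <- withCallingHandlers(
      {
        crd <- sample_chord(config$chord_matrix, pos, state)
        voicing <- choose_tenor_voicing(crd, prev_voicing, bounds)

        sop_lick <- sample_soprano_lick(config$lick_bank,
                                        arousal_rhythm_region(state),
                                        pos$bar_in_theme)
        alto_lick <- alto_onsets(roughness_from_arousal(state,
                                                        config$roughness_floor))

        bass_ev <- bass_note(crd)
        tenor_ev <- data.frame(voice = "tenor", pitch = as.integer(voicing),
                               onset = 0L, duration = SUBDIVISIONS,
                               stringsAsFactors = FALSE)
        sop_ev <- soprano_notes(crd, sop_lick, bounds)

        bar_tick <- (b - 1L) * SUBDIVISIONS
        sop_hist_tick <- c(sop_hist_tick, bar_tick + sop_ev$onset)
        sop_hist_pitch <- c(sop_hist_pitch, sop_ev$pitch)

        # alto line: one pitch per onset, step-motion transitions gated by
        # whether the governing soprano note has just changed pitch
        a_on <- lick_onsets(alto_lick)
        a_dur <- lick_durations(alto_lick)
        a_pitch <- integer(length(a_on))
        a_states <- character(length(a_on))
        a_changed <- logical(length(a_on))
        awin <- alto_window(bounds)
        for (k in seq_along(a_on)) {
          t <- bar_tick + a_on[[k]]
          gov <- if (length(sop_hist_tick)) max(0L, max(which(sop_hist_tick <= t), 0L)) else 0L
          changed <- gov >= 2L && gov != last_gov &&
            sop_hist_pitch[[gov]] != sop_hist_pitch[[gov - 1L]]
          if (gov > 0L) last_gov <- gov
          if (is.null(alto_pitch)) {
            reals <- chord_tone_pitches(crd, awin)
            alto_pitch <- reals[[sample.int(length(reals), 1L)]]
            alto_state <- "CT"
            changed <- FALSE
          } else if (alto_pitch < awin[["low"]] || alto_pitch > awin[["high"]]) {
            # register window moved with the valence region: re-seat the line
            # on the nearest chord tone inside the new window
            reals <- chord_tone_pitches(crd, awin)
            alto_pitch <- reals[[which.min(abs(reals - alto_pitch))]]
            alto_state <- "CT"
            changed <- FALSE
          } else {
            nxt <- next_alto_note(alto_pitch, alto_state, changed, crd,
                                  config$step_matrices[[
                                    arousal_melody_region(state) + 1L]],
                                  scale_pcs, bounds)
            alto_pitch <- nxt$pitch
            alto_state <- nxt$state
          }
          a_pitch[[k]] <- alto_pitch
          a_states[[k]] <- alto_state
          a_changed[[k]] <- changed
        }
        alto_ev <- data.frame(voice = "alto", pitch = a_pitch,
                              onset = as.integer(a_on),
                              duration = as.integer(a_dur),
                              stringsAsFactors = FALSE)

        dbl_ev <- marimba_doubling(state, sop_ev)
        velocity <- sample_bar_velocity(state, prev_velocity,
                                        config$velocity_delta)

        events <- rbind(bass_ev, tenor_ev, alto_ev, sop_ev, dbl_ev)
        events$velocity <- velocity

        list(position = pos, state = state, tempo = tempo, chord = crd,
             velocity = velocity, events = events, voicing = voicing,
             region = region, bounds = bounds,
             soprano_lick = sop_lick, alto_lick = alto_lick,
             alto_states = a_states, alto_changed = a_changed)
      },
      error = function(e) {
        stop(sprintf("bar %d: %s", b, conditionMessage(e)), call. = FALSE)
      })
    prev_voicing <- bar_plan$voicing
    prev_velocity <- bar_plan$velocity
    bars[[b]] <- bar_plan
  }

  structure(list(bars = bars, n_bars = n_bars, seed = seed,
                 ticks_per_quarter = 480L),
            class = "affect_score")
}

#' Marimba doubling of the soprano melody
#'
#' At high valence (valence >= 0.8) the marimba doubles the clarinet
#' melody note for note; below the threshold it is silent.
#'
#' @param state An [affect_state()].
#' @param soprano_events Data frame of soprano note events.
#' @param threshold Valence threshold at and above which doubling occurs.
#' @return Data frame of `soprano_double` note events (possibly zero rows).
#' @export
marimba_doubling <- function(state, soprano_events, threshold = 0.8) {
  state <- as_affect_state(state)
  if (state$valence >= threshold && nrow(soprano_events) > 0L) {
    out <- soprano_events
    out$voice <- "soprano_double"
    out
  } else {
    soprano_events[integer(), , drop = FALSE]
  }
}

#' @export
print.affect_score <- function(x, ...) {
  nev <- sum(vapply(x$bars, function(b) nrow(b$events), 0L))
  cat(sprintf("<affect_score> %d bars, %d note events%s\n", x$n_bars, nev,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  utils::head(summary(x), 4L)
}

#' @export
summary.affect_score <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$bars), function(b) {
    p <- object$bars[[b]]
    data.frame(bar = b, theme_bar = p$position$bar_in_theme,
               iteration = p$position$iteration,
               valence = p$state$valence, arousal = p$state$arousal,
               tempo = p$tempo, chord = p$chord$label,
               velocity = p$velocity, n_events = nrow(p$events),
               stringsAsFactors = FALSE)
  }))
}

#' Flatten a score to one row per note event
#'
#' @param x An `affect_score`.
#' @param ... Unused.
#' @return Data frame with columns `bar`, `voice`, `pitch`, `onset`
#'   (subdivision within the bar), `tick` (global, in subdivisions),
#'   `duration`, `velocity`.
#' @export
as.data.frame.affect_score <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$bars), function(b) {
    ev <- x$bars[[b]]$events
    if (nrow(ev) == 0L) return(NULL)
    ev$bar <- b
    ev$tick <- (b - 1L) * SUBDIVISIONS + ev$onset
    ev[, c("bar", "voice", "pitch", "onset", "tick", "duration", "velocity")]
  }))
}
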