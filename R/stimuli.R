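#' Default affect points for validation stimuli
#'
#' The 13 points covering the corners, quadrant middles, edge midpoints and
#' centre of the valence-arousal plane used to generate validation stimuli.
#'
#' @return Data frame with columns `valence` and `arousal` (13 rows).
#' @export
default_stimulus_points <- function() {
  data.frame(
    valence = c(0, 0, 0, 0.25, 0.25, 0.5, 0.5, 0.5, 0.75, 0.75, 1, 1, 1),
    arousal = c(0, 0.5, 1, 0.25, 0.75, 0, 0.5, 1, 0.25, 0.75, 0, 0.5, 1)
  )
}

#' Generate a batch of validation stimuli
#'
#' Produces `instances_per_point` MIDI files for each affect point, each
#' from its own derived seed (`seed + (point_index - 1) * 1000 + instance`)
#' so the whole batch is reproducible. Stimuli at a fast tempo
#' (>= `fast_tempo_bpm`, default 120 bpm) run 16 bars, others 8 bars, so
#' fast excerpts are not too brief while the theme still reaches its
#' cadence bar.
#'
#' @param points Data frame with columns `valence` and `arousal`; defaults
#'   to the 13 standard points.
#' @param instances_per_point Stimuli per point (default 3).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer base seed.
#' @param config See [am_config()].
#' @return Data frame manifest (one row per file): `point`, `instance`,
#'   `valence`, `arousal`, `n_bars`, `seed`, `file`.
#' @export
generate_stimuli <- function(points = default_stimulus_points(),
                             instances_per_point = 3L, out_dir, seed = 1L,
                             config = NULL) {
  config <- am_config(config)
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("valence", "arousal") %in% names(points)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(points))) {
    st <- affect_state(points$valence[[i]], points$arousal[[i]])
    tempo <- tempo_from_arousal(st, config$tempo[["min_bpm"]],
                                config$tempo[["max_bpm"]])
    n_bars <- if (tempo >= config$fast_tempo_bpm) 16L else 8L
    for (j in seq_len(instances_per_point)) {
      s <- as.integer(seed) + (i - 1L) * 1000L + j
      f <- file.path(out_dir, sprintf("stimulus_v%03d_a%03d_i%d.mid",
                                      round(st$valence * 100),
                                      round(st$arousal * 100), j))
      score <- generate(st, n_bars = n_bars, seed = s, config = config)
      write_midi(score, f)
      rows[[length(rows) + 1L]] <- data.frame(
        point = i, instance = j, valence = st$valence, arousal = st$arousal,
        n_bars = n_bars, seed = s, file = f, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
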