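.am_env <- new.env(parent = emptyenv())

#' Path to the shipped default configuration
#'
#' The default configuration is a YAML file holding every data-driven piece
#' of the generator: the 10 x 8 probabilistic chord matrix, the soprano lick
#' bank, the alto step-motion transition matrices, the per-region register
#' bounds, and the scalar mapping constants (tempo endpoints, velocity-change
#' caps, roughness floor, fast-tempo stimulus threshold, tonic). Users can
#' copy and edit it, then pass the edited path to [am_config()].
#'
#' @return File path of the installed default configuration.
#' @export
default_config_path <- function() {
  p <- system.file("extdata", "default_config.yaml", package = "affectmusic")
  if (!nzchar(p)) stop("default configuration not found in installed package")
  p
}

#' Load and validate a generator configuration
#'
#' Reads a YAML (or JSON) configuration file, fills any missing sections
#' from the shipped defaults, and validates every data structure: the chord
#' matrix (cell probabilities, candidate counts, bar-8 cadences, dissonance
#' gradient), the lick bank (two length-8 binary licks per arousal region
#' and theme bar) and the step transition matrices (row-stochastic 4 x 4).
#'
#' @param path Path to a configuration file, or `NULL` for the shipped
#'   defaults.
#' @return An object of class `am_config`: a list with elements
#'   `tempo` (`c(min_bpm, max_bpm)`), `velocity_delta` (`c(min, max)`),
#'   `roughness_floor`, `fast_tempo_bpm`, `tonic`, `register_table`
#'   (10 x 2 integer matrix), `step_matrices` (list `low`/`high` of 4 x 4
#'   matrices), `lick_bank` and `chord_matrix`.
#' @export
am_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.am_env$default_config)) return(.am_env$default_config)
    raw <- yaml::read_yaml(default_config_path())
  } else {
    if (inherits(path, "am_config")) return(path)
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    raw <- yaml::read_yaml(default_config_path())
    for (nm in names(user)) raw[[nm]] <- user[[nm]]  # sections replace wholesale
  }
  cfg <- parse_config(raw)
  if (is.null(path)) .am_env$default_config <- cfg
  cfg
}

parse_config <- function(raw) {
  need <- c("tempo", "velocity_delta", "roughness", "register_bounds",
            "step_matrices", "licks", "chord_matrix")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("config is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  reg <- raw$register_bounds
  if (length(reg) != 10L || !all(vapply(reg, length, 0L) == 2L))
    stop("config: register_bounds must be 10 pairs of MIDI pitches", call. = FALSE)
  reg <- matrix(as.integer(unlist(reg)), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("low", "high")))
  if (any(reg < 0L | reg > 127L) || any(reg[, 1] >= reg[, 2]))
    stop("config: register_bounds rows must satisfy 0 <= low < high <= 127",
         call. = FALSE)
  structure(list(
    tempo = c(min_bpm = as.numeric(raw$tempo$min_bpm),
              max_bpm = as.numeric(raw$tempo$max_bpm)),
    velocity_delta = c(min = as.numeric(raw$velocity_delta$min),
                       max = as.numeric(raw$velocity_delta$max)),
    roughness_floor = as.numeric(raw$roughness$floor),
    fast_tempo_bpm = as.numeric(raw$fast_tempo_bpm %||% 120),
    tonic = as.integer(raw$tonic %||% 0L),
    register_table = reg,
    step_matrices = load_step_matrices(raw$step_matrices),
    lick_bank = load_lick_bank(raw$licks),
    chord_matrix = load_chord_matrix(raw$chord_matrix)
  ), class = "am_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.am_config <- function(x, ...) {
  cat("<am_config>\n",
      sprintf("  tempo %g-%g bpm; velocity delta %g-%g; roughness floor %g\n",
              x$tempo[[1]], x$tempo[[2]], x$velocity_delta[[1]],
              x$velocity_delta[[2]], x$roughness_floor),
      "  chord matrix: 10 regions x 8 bars; lick bank: 3 regions x 8 bars x 2\n")
  invisible(x)
}

# ---- chord matrix -----------------------------------------------------------

#' Load and validate a chord matrix
#'
#' The chord matrix assigns, to each of the 10 valence regions and each of
#' the 8 bars of the looping theme, a small categorical distribution over
#' chords. Validation enforces: 1--5 candidates per cell; probabilities in
#' \[0.1, 0.8\] (a singleton cell may carry probability 1) summing to 1
#' within 1e-9; every bar-8 candidate cadential; and the dissonance
#' gradient -- the probability-weighted expected [dissonance_score()] of
#' each cell is nonincreasing as the valence region rises, bar by bar.
#'
#' @param x A nested list `{region: {bar: [{root, quality, prob, label,
#'   cadential}, ...]}}` (region keys "0".."9", bar keys "1".."8"), or a
#'   path to a YAML/JSON file holding one under a `chord_matrix` key or at
#'   top level.
#' @return An object of class `am_chord_matrix`.
#' @export
load_chord_matrix <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    raw <- yaml::read_yaml(x)
    x <- raw$chord_matrix %||% raw
  }
  if (!is.list(x)) stop("chord matrix config must be a nested list", call. = FALSE)
  missing_r <- setdiff(as.character(0:9), names(x))
  if (length(missing_r))
    stop("chord matrix config: missing valence region(s) ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  cells <- vector("list", 10L)
  problems <- character()
  for (r in 0:9) {
    reg <- x[[as.character(r)]]
    cells[[r + 1L]] <- vector("list", 8L)
    missing_b <- setdiff(as.character(1:8), names(reg))
    if (length(missing_b)) {
      problems <- c(problems, sprintf("region %d: missing bar(s) %s", r,
                                      paste(missing_b, collapse = ", ")))
      next
    }
    for (b in 1:8) {
      entries <- reg[[as.character(b)]]
      tag <- sprintf("region %d bar %d", r, b)
      if (length(entries) < 1L || length(entries) > 5L) {
        problems <- c(problems, paste0(tag, ": needs 1-5 candidates, has ",
                                       length(entries)))
        next
      }
      chords <- lapply(entries, function(e) {
        chord(e$root, e$quality, e$label, isTRUE(e$cadential))
      })
      prob <- vapply(entries, function(e) as.numeric(e$prob), 0)
      if (abs(sum(prob) - 1) > 1e-9)
        problems <- c(problems, sprintf("%s: probabilities sum to %g", tag, sum(prob)))
      ok_range <- if (length(prob) == 1L) {
        abs(prob - 1) < 1e-9 || (prob >= 0.1 - 1e-9 && prob <= 0.8 + 1e-9)
      } else {
        all(prob >= 0.1 - 1e-9 & prob <= 0.8 + 1e-9)
      }
      if (!ok_range)
        problems <- c(problems, sprintf("%s: probability outside [0.1, 0.8]", tag))
      if (b == 8L && !all(vapply(chords, function(ch) ch$cadential, TRUE)))
        problems <- c(problems, paste0(tag, ": non-cadential candidate in bar 8"))
      cells[[r + 1L]][[b]] <- list(chords = chords, prob = prob)
    }
  }
  if (length(problems))
    stop("chord matrix validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  m <- structure(list(cells = cells), class = "am_chord_matrix")
  ed <- expected_cell_dissonance(m)
  for (b in 1:8) {
    if (any(diff(ed[, b]) > 1e-9))
      problems <- c(problems,
                    sprintf("bar %d: expected dissonance not nonincreasing across valence regions", b))
  }
  if (length(problems))
    stop("chord matrix validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  m
}

#' Expected dissonance of every chord-matrix cell
#'
#' @param matrix An `am_chord_matrix`.
#' @return A 10 x 8 numeric matrix (regions x theme bars) of
#'   probability-weighted expected [dissonance_score()] values.
#' @export
expected_cell_dissonance <- function(matrix) {
  stopifnot(inherits(matrix, "am_chord_matrix"))
  out <- matrix(NA_real_, nrow = 10L, ncol = 8L,
                dimnames = list(region = 0:9, bar = 1:8))
  for (r in 1:10) {
    for (b in 1:8) {
      cell <- matrix$cells[[r]][[b]]
      out[r, b] <- sum(cell$prob *
                         vapply(cell$chords, dissonance_score, 0L))
    }
  }
  out
}

#' @export
print.am_chord_matrix <- function(x, ...) {
  n <- sum(vapply(x$cells, function(reg)
    sum(vapply(reg, function(cell) length(cell$chords), 0L)), 0L))
  cat(sprintf("<am_chord_matrix> 10 regions x 8 bars, %d chord candidates\n", n))
  invisible(x)
}

# ---- step matrices ----------------------------------------------------------

step_states <- c("-1", "+1", "0", "CT")

#' Load and validate alto step-motion transition matrices
#'
#' One 4 x 4 row-stochastic matrix per arousal melody region. States, in
#' fixed order: `-1` (diatonic step down), `+1` (diatonic step up), `0`
#' (repeat pitch), `CT` (jump to a random chord tone).
#'
#' @param x A list with elements `low` and `high`, each a list of 4 numeric
#'   rows of length 4 (row/column order -1, +1, 0, CT).
#' @return Named list of two 4 x 4 matrices with dimnames set to the states.
#' @export
load_step_matrices <- function(x) {
  if (!all(c("low", "high") %in% names(x)))
    stop("step_matrices config needs elements 'low' and 'high'", call. = FALSE)
  out <- lapply(x[c("low", "high")], function(rows) {
    if (length(rows) != 4L || !all(vapply(rows, length, 0L) == 4L))
      stop("each step matrix must be 4 x 4", call. = FALSE)
    m <- matrix(as.numeric(unlist(rows)), nrow = 4L, byrow = TRUE,
                dimnames = list(step_states, step_states))
    if (any(m < 0)) stop("step matrix entries must be nonnegative", call. = FALSE)
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop("step matrix rows must sum to 1", call. = FALSE)
    m
  })
  names(out) <- c("low", "high")
  out
}

# ---- lick bank --------------------------------------------------------------

#' Load and validate the soprano lick bank
#'
#' For each arousal rhythm region (low/moderate/high) and each theme bar,
#' exactly two stored rhythmic patterns ("licks") of 8 binary values on the
#' eighth-note grid, each with at least one onset.
#'
#' @param x A nested list `{low|moderate|high: {bar: [lick, lick]}}`.
#' @return An object of class `am_lick_bank`.
#' @export
load_lick_bank <- function(x) {
  regions <- c("low", "moderate", "high")
  if (!all(regions %in% names(x)))
    stop("lick bank config needs regions low, moderate, high", call. = FALSE)
  bank <- lapply(x[regions], function(reg) {
    missing_b <- setdiff(as.character(1:8), names(reg))
    if (length(missing_b))
      stop("lick bank: missing bar(s) ", paste(missing_b, collapse = ", "),
           call. = FALSE)
    lapply(as.character(1:8), function(b) {
      licks <- reg[[b]]
      if (length(licks) != 2L)
        stop("lick bank: every cell needs exactly 2 licks (bar ", b, ")",
             call. = FALSE)
      lapply(licks, function(l) {
        l <- as.integer(l)
        if (length(l) != 8L || !all(l %in% c(0L, 1L)) || sum(l) < 1L)
          stop("lick must be 8 binary values with at least one onset",
               call. = FALSE)
        l
      })
    })
  })
  structure(list(bank = bank), class = "am_lick_bank")
}

#' @export
print.am_lick_bank <- function(x, ...) {
  cat("<am_lick_bank> 3 arousal regions x 8 theme bars x 2 licks\n")
  invisible(x)
}
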