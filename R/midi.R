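#' Default instrument map
#'
#' Voices are rendered by four General-MIDI instruments on distinct
#' channels: bass by a string ensemble, the two inner voices (tenor
#' voicing, alto line) by piano, the soprano melody by clarinet, and its
#' high-valence doubling by marimba.
#'
#' @return Data frame with columns `voice`, `instrument`, `channel` (0-based
#'   MIDI channel) and `program` (General-MIDI program number, 0-based).
#' @export
default_instrument_map <- function() {
  data.frame(
    voice      = c("bass", "tenor", "alto", "soprano", "soprano_double"),
    instrument = c("strings", "piano", "piano", "clarinet", "marimba"),
    channel    = c(0L, 1L, 1L, 2L, 3L),
    program    = c(48L, 0L, 0L, 71L, 12L),
    stringsAsFactors = FALSE
  )
}

TICKS_PER_EIGHTH <- 240L  # ticks-per-quarter 480, eighth-note grid

#' Timestamped MIDI event stream of a score
#'
#' The canonical event sequence of a score: one conductor track carrying a
#' tempo meta-event at every bar where the tempo changes, and one track per
#' instrument carrying its program change and note on/off events. This same
#' sequence is what [write_midi()] serialises, and is the real-time
#' streaming contract: feed it to [stream_events()] to deliver events to a
#' callback.
#'
#' @param score An `affect_score` from [generate()].
#' @param instrument_map See [default_instrument_map()].
#' @return Data frame with columns `track` (1 = conductor), `tick`
#'   (480 ticks per quarter note), `event` (`"tempo"`, `"program_change"`,
#'   `"note_on"`, `"note_off"`), `channel` (NA for tempo), `value1`
#'   (microseconds per quarter / program / pitch) and `value2` (velocity;
#'   0 for note_off, NA otherwise), ordered by track, tick and event
#'   priority (program change, then note offs, then note ons).
#' @export
midi_event_stream <- function(score, instrument_map = default_instrument_map()) {
  stopifnot(inherits(score, "affect_score"))
  if (length(score$bars) == 0L) stop("empty score", call. = FALSE)
  instruments <- unique(instrument_map$instrument)
  inst_track <- stats::setNames(seq_along(instruments) + 1L, instruments)
  voice_inst <- stats::setNames(instrument_map$instrument, instrument_map$voice)
  voice_chan <- stats::setNames(instrument_map$channel, instrument_map$voice)
  inst_chan <- stats::setNames(instrument_map$channel, instrument_map$instrument)
  inst_prog <- stats::setNames(instrument_map$program, instrument_map$instrument)
  if (anyDuplicated(instrument_map$channel[!duplicated(instrument_map$instrument)]))
    stop("instrument map must assign distinct channels per instrument",
         call. = FALSE)

  rows <- list()
  add <- function(track, tick, event, channel, value1, value2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      track = as.integer(track), tick = as.integer(tick), event = event,
      channel = as.integer(channel), value1 = as.integer(value1),
      value2 = as.integer(value2), stringsAsFactors = FALSE)
  }

  # conductor track: tempo changes at bar starts
  prev_tempo <- NA_real_
  for (b in seq_along(score$bars)) {
    tempo <- score$bars[[b]]$tempo
    if (is.na(prev_tempo) || tempo != prev_tempo) {
      add(1L, (b - 1L) * 8L * TICKS_PER_EIGHTH, "tempo", NA_integer_,
          round(6e7 / tempo), NA_integer_)
      prev_tempo <- tempo
    }
  }

  # program changes at track start
  for (inst in instruments)
    add(inst_track[[inst]], 0L, "program_change", inst_chan[[inst]],
        inst_prog[[inst]], NA_integer_)

  ev <- as.data.frame(score)
  for (i in seq_len(nrow(ev))) {
    v <- ev$voice[[i]]
    trk <- inst_track[[voice_inst[[v]]]]
    chan <- voice_chan[[v]]
    on_tick <- ev$tick[[i]] * TICKS_PER_EIGHTH
    off_tick <- on_tick + ev$duration[[i]] * TICKS_PER_EIGHTH
    add(trk, on_tick, "note_on", chan, ev$pitch[[i]], ev$velocity[[i]])
    add(trk, off_tick, "note_off", chan, ev$pitch[[i]], 0L)
  }

  out <- do.call(rbind, rows)
  prio <- c(program_change = 0L, tempo = 0L, note_off = 1L, note_on = 2L)
  out <- out[order(out$track, out$tick, prio[out$event], out$value1), ]
  rownames(out) <- NULL
  out
}

#' Deliver a score's events to a callback in time order
#'
#' The real-time contract: the callback receives each event (a one-row data
#' frame slice of [midi_event_stream()]) in nondecreasing tick order.
#'
#' @param score An `affect_score`.
#' @param callback Function of one argument.
#' @param instrument_map See [default_instrument_map()].
#' @return Invisibly, the number of events delivered.
#' @export
stream_events <- function(score, callback,
                          instrument_map = default_instrument_map()) {
  ev <- midi_event_stream(score, instrument_map)
  ev <- ev[order(ev$tick, ev$track), ]
  for (i in seq_len(nrow(ev))) callback(ev[i, ])
  invisible(nrow(ev))
}

# ---- standard MIDI file encoding -------------------------------------------

uint_bytes <- function(x, width) {
  x <- as.numeric(x)
  out <- raw(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

encode_varlen <- function(x) {
  x <- as.numeric(x)
  stopifnot(x >= 0)
  bytes <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    bytes <- c(as.raw(128 + x %% 128), bytes)
    x <- x %/% 128
  }
  bytes
}

encode_track <- function(ev) {
  chunks <- list()
  tick <- 0L
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[[i]] - tick
    tick <- ev$tick[[i]]
    body <- switch(ev$event[[i]],
      tempo = c(as.raw(c(0xFF, 0x51, 0x03)), uint_bytes(ev$value1[[i]], 3L)),
      program_change = c(as.raw(0xC0 + ev$channel[[i]]),
                         as.raw(ev$value1[[i]])),
      note_on = c(as.raw(0x90 + ev$channel[[i]]), as.raw(ev$value1[[i]]),
                  as.raw(ev$value2[[i]])),
      note_off = c(as.raw(0x80 + ev$channel[[i]]), as.raw(ev$value1[[i]]),
                   as.raw(ev$value2[[i]])),
      stop("unknown event type ", ev$event[[i]]))
    chunks[[length(chunks) + 1L]] <- c(encode_varlen(delta), body)
  }
  chunks[[length(chunks) + 1L]] <- as.raw(c(0x00, 0xFF, 0x2F, 0x00))
  payload <- do.call(c, chunks)
  c(charToRaw("MTrk"), uint_bytes(length(payload), 4L), payload)
}

#' Write a score to a standard MIDI file
#'
#' Serialises the score's event stream as a format-1 standard MIDI file:
#' one conductor track with tempo meta-events, one track per instrument
#' with a program change at its start and paired note on/off events, at
#' 480 ticks per quarter note. All timing is integer tick arithmetic, so
#' output is identical across platforms for identical inputs.
#'
#' @param score An `affect_score` from [generate()].
#' @param path Output file path.
#' @param instrument_map See [default_instrument_map()].
#' @return `path`, invisibly.
#' @export
write_midi <- function(score, path, instrument_map = default_instrument_map()) {
  ev <- midi_event_stream(score, instrument_map)
  tracks <- sort(unique(ev$track))
  header <- c(charToRaw("MThd"), uint_bytes(6L, 4L), uint_bytes(1L, 2L),
              uint_bytes(length(tracks), 2L),
              uint_bytes(score$ticks_per_quarter, 2L))
  body <- lapply(tracks, function(t)
    encode_track(ev[ev$track == t, , drop = FALSE]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, c(list(header), body)), con)
  invisible(path)
}

# ---- standard MIDI file decoding -------------------------------------------

bytes_uint <- function(raw) sum(as.numeric(raw) * 256^rev(seq_along(raw) - 1L))

#' Read a standard MIDI file
#'
#' Minimal reader for the subset of the format that [write_midi()] emits
#' (plus running status): tempo meta-events, program changes and note
#' on/off. Other meta and channel messages are skipped.
#'
#' @param path Path to a standard MIDI file.
#' @return List with `format`, `n_tracks`, `ticks_per_quarter` and `events`
#'   -- a data frame in the same layout as [midi_event_stream()].
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:4]), "MThd")) stop("not a MIDI file", call. = FALSE)
  fmt <- bytes_uint(raw[9:10])
  n_tracks <- bytes_uint(raw[11:12])
  tpq <- bytes_uint(raw[13:14])
  pos <- 15L
  rows <- list()
  for (trk in seq_len(n_tracks)) {
    if (!identical(rawToChar(raw[pos:(pos + 3L)]), "MTrk"))
      stop("malformed track header", call. = FALSE)
    len <- bytes_uint(raw[(pos + 4L):(pos + 7L)])
    p <- pos + 8L
    end <- p + len
    tick <- 0
    status <- NULL
    while (p < end) {
      # variable-length delta time
      delta <- 0
      repeat {
        b <- as.integer(raw[p]); p <- p + 1L
        delta <- delta * 128 + (b %% 128)
        if (b < 128) break
      }
      tick <- tick + delta
      b <- as.integer(raw[p])
      if (b >= 128) { status <- b; p <- p + 1L } # else: running status
      if (status == 0xFF) {
        type <- as.integer(raw[p]); p <- p + 1L
        mlen <- 0
        repeat {
          mb <- as.integer(raw[p]); p <- p + 1L
          mlen <- mlen * 128 + (mb %% 128)
          if (mb < 128) break
        }
        if (type == 0x51) {
          rows[[length(rows) + 1L]] <- data.frame(
            track = trk, tick = as.integer(tick), event = "tempo",
            channel = NA_integer_,
            value1 = as.integer(bytes_uint(raw[p:(p + mlen - 1L)])),
            value2 = NA_integer_, stringsAsFactors = FALSE)
        }
        p <- p + mlen
      } else {
        hi <- status %/% 16L
        chan <- status %% 16L
        if (hi == 0x9 || hi == 0x8) {
          pitch <- as.integer(raw[p]); vel <- as.integer(raw[p + 1L])
          p <- p + 2L
          rows[[length(rows) + 1L]] <- data.frame(
            track = trk, tick = as.integer(tick),
            event = if (hi == 0x9 && vel > 0L) "note_on" else "note_off",
            channel = chan, value1 = pitch, value2 = vel,
            stringsAsFactors = FALSE)
        } else if (hi == 0xC) {
          rows[[length(rows) + 1L]] <- data.frame(
            track = trk, tick = as.integer(tick), event = "program_change",
            channel = chan, value1 = as.integer(raw[p]),
            value2 = NA_integer_, stringsAsFactors = FALSE)
          p <- p + 1L
        } else if (hi == 0xD) {
          p <- p + 1L
        } else {
          p <- p + 2L  # other two-byte channel messages
        }
      }
    }
    pos <- end
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  list(format = fmt, n_tracks = n_tracks, ticks_per_quarter = tpq,
       events = events)
}
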