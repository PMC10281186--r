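test_that("generation cycles the 8-bar theme and is deterministic under a seed", {
  s <- generate(c(0.6, 0.4), n_bars = 8, seed = 10)
  expect_equal(vapply(s$bars, function(b) b$position$bar_in_theme, 0L), 1:8)
  s24 <- generate(c(0.6, 0.4), n_bars = 24, seed = 10)
  expect_equal(s24$bars[[24]]$position$iteration, 2L)  # third theme iteration
  expect_identical(generate(c(0.2, 0.9), 10, seed = 3),
                   generate(c(0.2, 0.9), 10, seed = 3))
})

test_that("every bar plan is internally consistent", {
  set.seed(17); traj <- data.frame(valence = runif(30), arousal = runif(30))
  s <- generate(traj, n_bars = 30, seed = 5)
  for (b in seq_along(s$bars)) {
    p <- s$bars[[b]]
    expect_equal(p$tempo, tempo_from_arousal(p$state))
    expect_true(all(p$events$velocity == p$velocity))
    expect_true(all(p$events$pitch >= 0 & p$events$pitch <= 127))
    expect_true(all(p$events$onset + p$events$duration <= 8))
    expect_true(all(diff(p$voicing) > 0))  # tenor voicing strictly ascending
    vr <- velocity_range(p$state)
    expect_true(p$velocity >= round(vr[["low"]]) &&
                  p$velocity <= round(vr[["high"]]))
  }
})

test_that("voice-leading properties hold over a long seeded run", {
  set.seed(2024)
  traj <- data.frame(valence = runif(1000), arousal = runif(1000))
  s <- generate(traj, n_bars = 1000, seed = 77)

  # alto step rule: a melody change forces a single diatonic step
  violations <- 0L
  for (b in seq_along(s$bars)) {
    p <- s$bars[[b]]
    alto <- p$events[p$events$voice == "alto", ]
    scale_pcs <- scale_for_region(p$region)
    prev_pitch <- if (b == 1L) NULL else {
      pe <- s$bars[[b - 1L]]$events
      utils::tail(pe$pitch[pe$voice == "alto"], 1)
    }
    for (k in seq_len(nrow(alto))) {
      if (p$alto_changed[[k]]) {
        cur <- alto$pitch[[k]]
        before <- if (k > 1L) alto$pitch[[k - 1L]] else prev_pitch
        expect_true(p$alto_states[[k]] %in% c("-1", "+1"))
        if (!is.null(before)) {
          dir <- if (p$alto_states[[k]] == "-1") -1L else 1L
          if (!identical(cur, diatonic_step(before, dir, scale_pcs)))
            violations <- violations + 1L
        }
      }
    }
  }
  expect_equal(violations, 0L)

  # consecutive-bar parallel perfect fifths between bass and alto are rare
  downbeats <- t(vapply(s$bars, function(p) {
    c(bass = p$events$pitch[p$events$voice == "bass"][[1]],
      alto = p$events$pitch[p$events$voice == "alto"][[1]])
  }, c(bass = 0L, alto = 0L)))
  fifth <- (downbeats[, "alto"] - downbeats[, "bass"]) %% 12 == 7
  moved <- diff(downbeats[, "bass"]) != 0 & diff(downbeats[, "alto"]) != 0
  parallel <- fifth[-1] & fifth[-length(fifth)] & moved
  expect_lt(mean(parallel), 0.10)

  # all pitches inside the per-bar register bounds (bass excepted: fixed C3)
  for (p in s$bars) {
    upper <- p$events[p$events$voice != "bass", ]
    expect_true(all(upper$pitch >= p$bounds[["low"]] &
                      upper$pitch <= p$bounds[["high"]]))
  }
})

test_that("marimba doubles the soprano at and above valence 0.8", {
  sop <- data.frame(voice = "soprano", pitch = c(72L, 76L, 79L, 72L),
                    onset = c(0L, 2L, 4L, 6L), duration = c(2L, 2L, 2L, 2L))
  d <- marimba_doubling(affect_state(0.8, 0.5), sop)
  expect_equal(nrow(d), 4L)
  expect_true(all(d$voice == "soprano_double"))
  expect_equal(d$pitch, sop$pitch)
  expect_equal(d$onset, sop$onset)
  expect_equal(nrow(marimba_doubling(affect_state(0.79, 0.5), sop)), 0L)
  expect_equal(nrow(marimba_doubling(affect_state(1, 0.5), sop)), 4L)
})

test_that("MIDI files round-trip to the identical event stream", {
  s <- generate(c(0.5, 0.5), n_bars = 8, seed = 9)
  f <- tempfile(fileext = ".mid")
  write_midi(s, f)
  m <- read_midi(f)
  expect_equal(m$format, 1)
  expect_equal(m$ticks_per_quarter, 480)
  expect_identical(m$events, midi_event_stream(s))
  # per-track timestamps are monotone
  for (trk in unique(m$events$track))
    expect_true(all(diff(m$events$tick[m$events$track == trk]) >= 0))
  unlink(f)
})

test_that("a step in arousal writes the matching tempo meta-events", {
  traj <- data.frame(bar = c(1, 5), valence = c(0.5, 0.5), arousal = c(0, 1))
  s <- generate(traj, n_bars = 8, seed = 2)
  ev <- midi_event_stream(s)
  tempos <- ev[ev$event == "tempo", ]
  expect_equal(nrow(tempos), 2L)
  expect_equal(tempos$value1, as.integer(round(6e7 / c(60, 200))))
  expect_equal(tempos$tick, c(0L, 4L * 8L * 240L))
})

test_that("below the doubling threshold the marimba track is silent", {
  s <- generate(c(0.5, 0.5), n_bars = 8, seed = 4)
  ev <- midi_event_stream(s)
  imap <- default_instrument_map()
  marimba_chan <- imap$channel[imap$instrument == "marimba"]
  notes <- ev[ev$event == "note_on" & !is.na(ev$channel) &
                ev$channel == marimba_chan, ]
  expect_equal(nrow(notes), 0L)
  # but the track itself exists, carrying its program change
  expect_true(any(ev$event == "program_change" & ev$channel == marimba_chan))
})

test_that("the streaming contract delivers the file's events in time order", {
  s <- generate(c(0.9, 0.9), n_bars = 4, seed = 6)
  seen <- list()
  n <- stream_events(s, function(e) seen[[length(seen) + 1L]] <<- e)
  expect_equal(n, nrow(midi_event_stream(s)))
  ticks <- vapply(seen, function(e) e$tick, 0L)
  expect_true(all(diff(ticks) >= 0))
  got <- do.call(rbind, seen)
  ref <- midi_event_stream(s)
  expect_setequal(do.call(paste, got), do.call(paste, ref))
})

test_that("stimulus batches derive seeds per instance and size bars by tempo", {
  out <- tempfile("stims")
  pts <- data.frame(valence = c(0, 0.5), arousal = c(1, 0))
  man <- generate_stimuli(pts, instances_per_point = 2, out_dir = out, seed = 100)
  expect_equal(nrow(man), 4L)
  expect_true(all(file.exists(man$file)))
  expect_equal(man$n_bars, c(16L, 16L, 8L, 8L))  # arousal 1 is fast, 0 is slow
  expect_equal(man$seed, c(101L, 102L, 1101L, 1102L))
  unlink(out, recursive = TRUE)
})

test_that("generation errors carry the offending bar index", {
  cfg_raw <- yaml::read_yaml(default_config_path())
  cfg_raw$register_bounds[[10]] <- c(60, 79)  # tenor window too narrow
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_raw, f)
  traj <- data.frame(bar = c(1, 3), valence = c(0.5, 0.95),
                     arousal = c(0.5, 0.5))
  expect_error(generate(traj, n_bars = 4, seed = 1, config = f), "bar 3")
  unlink(f)
})
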