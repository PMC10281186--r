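test_that("voicing dissimilarity is the all-pairs absolute-difference sum", {
  expect_equal(voicing_dissimilarity(60, 60), 0)
  expect_equal(voicing_dissimilarity(60, 62), 2)
  n <- c(60, 64, 67); np <- c(59, 62, 67)
  expect_equal(voicing_dissimilarity(n, np), oracle_dissimilarity(n, np))
  # note: the all-pairs sum is nonzero even for identical multi-note sets
  expect_gt(voicing_dissimilarity(n, n), 0)
  set.seed(8)
  for (i in 1:25) {
    a <- sample(40:80, sample(2:4, 1))
    b <- sample(40:80, sample(2:4, 1))
    expect_equal(voicing_dissimilarity(a, b), oracle_dissimilarity(a, b))
    expect_equal(voicing_dissimilarity(a, b), voicing_dissimilarity(b, a))
  }
  expect_error(voicing_dissimilarity(numeric(0), 60), "non-empty")
})

test_that("tenor voicing choice minimises dissimilarity over the enumeration", {
  bounds <- c(low = 24L, high = 72L)
  win <- c(24 + 12, 72 - 5)
  set.seed(21)
  for (i in 1:30) {
    prev_chord <- chord(sample(0:11, 1), sample(c("major", "minor", "dominant7"), 1))
    cur_chord <- chord(sample(0:11, 1), sample(c("major", "minor", "diminished",
                                                 "minor7", "major7"), 1))
    prev <- choose_tenor_voicing(prev_chord, NULL, bounds)
    chosen <- choose_tenor_voicing(cur_chord, prev, bounds)
    expect_identical(chosen, oracle_best_voicing(cur_chord, prev, win))
  }
})

test_that("a single-candidate window returns its voicing regardless of previous", {
  # window of exactly one octave realizes each pitch class exactly once
  crd <- chord(0, "major")
  cands <- enumerate_voicings(crd, c(60, 71))
  expect_length(cands, 1L)
  bounds <- c(low = 48L, high = 76L)  # tenor window [60, 71]
  expect_identical(choose_tenor_voicing(crd, c(30, 40, 50), bounds), cands[[1]])
  expect_identical(choose_tenor_voicing(crd, c(90, 100), bounds), cands[[1]])
})

test_that("no voicing in the window is an informative error", {
  crd <- chord(0, "dominant7")
  expect_error(choose_tenor_voicing(crd, NULL, c(low = 40L, high = 57L)),
               "no voicing")
})

test_that("alto motion follows the sampled state and steps with the melody", {
  cfg <- am_config()
  m <- cfg$step_matrices$high
  scale_pcs <- scale_for_region(7)
  bounds <- c(low = 30L, high = 90L)
  crd <- chord(7, "major")
  set.seed(31)
  for (i in 1:200) {
    cur <- sample(55:70, 1)
    nxt <- next_alto_note(cur, "0", TRUE, crd, m, scale_pcs, bounds)
    expect_true(nxt$state %in% c("-1", "+1"))
    dir <- if (nxt$state == "-1") -1L else 1L
    expect_equal(nxt$pitch, diatonic_step(cur, dir, scale_pcs))
    expect_false(nxt$pitch == cur)
  }
  # a degenerate matrix pinned on "0" never moves
  pin <- matrix(0, 4, 4, dimnames = list(c("-1", "+1", "0", "CT"),
                                         c("-1", "+1", "0", "CT")))
  pin[, "0"] <- 1
  for (i in 1:20) {
    nxt <- next_alto_note(64L, sample(c("-1", "+1", "0", "CT"), 1), FALSE,
                          crd, pin, scale_pcs, bounds)
    expect_equal(nxt$pitch, 64L)
    expect_equal(nxt$state, "0")
  }
})

test_that("alto steps reflect at the register boundary instead of clamping", {
  pin <- matrix(0, 4, 4, dimnames = list(c("-1", "+1", "0", "CT"),
                                         c("-1", "+1", "0", "CT")))
  pin[, "+1"] <- 1  # always try to step up
  scale_pcs <- scale_for_region(9)
  bounds <- c(low = 48L, high = 62L)  # alto window [60, 62]
  crd <- chord(0, "major")
  set.seed(4)
  nxt <- next_alto_note(62L, "0", FALSE, crd, pin, scale_pcs, bounds)
  expect_equal(nxt$state, "-1")      # reflected downwards
  expect_lt(nxt$pitch, 62L)
})

test_that("diatonic steps land on the adjacent scale degree", {
  maj <- scale_for_region(9)  # C major
  expect_equal(diatonic_step(60, 1, maj), 62)   # C4 -> D4
  expect_equal(diatonic_step(64, 1, maj), 65)   # E4 -> F4
  expect_equal(diatonic_step(60, -1, maj), 59)  # C4 -> B3
  minor <- scale_for_region(0)  # C natural minor
  expect_equal(diatonic_step(62, 1, minor), 63)  # D4 -> Eb4
  # off-scale starting point still lands on the nearest scale tone
  expect_equal(diatonic_step(61, 1, maj), 62)
})

test_that("soprano notes are chord tones inside the register bounds", {
  cfg <- am_config()
  set.seed(12)
  for (i in 1:200) {
    v <- runif(1)
    st <- affect_state(v, runif(1))
    bounds <- register_bounds(st)
    crd <- sample_chord(cfg$chord_matrix, sample(1:8, 1), st)
    lick <- sample_soprano_lick(cfg$lick_bank, arousal_rhythm_region(st),
                                sample(1:8, 1))
    ev <- soprano_notes(crd, lick, bounds)
    expect_equal(nrow(ev), sum(lick))
    expect_true(all(ev$pitch %% 12 %in% crd$tones))
    expect_true(all(ev$pitch >= bounds[["low"]] & ev$pitch <= bounds[["high"]]))
    expect_true(all(ev$onset + ev$duration <= 8L))
  }
  # a 4-onset lick yields exactly 4 events
  ev <- soprano_notes(chord(0, "major"), c(1, 0, 1, 0, 1, 0, 1, 0),
                      c(low = 24L, high = 72L))
  expect_equal(nrow(ev), 4L)
})

test_that("the bass always plays the chord root in the C3 octave", {
  expect_equal(bass_note(chord(0, "major"))$pitch, 48L)
  expect_equal(bass_note(chord(9, "minor"))$pitch, 57L)
  ev <- bass_note(chord(5, "minor"))
  expect_equal(ev$onset, 0L)
  expect_equal(ev$duration, 8L)
  expect_identical(bass_note(chord(5, "minor")), ev)  # deterministic
  for (pc in 0:11)
    expect_true(bass_note(chord(pc, "major"))$pitch %in% 48:59)
})
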