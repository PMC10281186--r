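test_that("affect states clamp in streaming mode and reject in batch mode", {
  expect_error(affect_state(1.2, 0.5), "\\[0, 1\\]")
  expect_error(affect_state(0.5, -0.01), "\\[0, 1\\]")
  st <- affect_state(1.2, -0.3, clamp = TRUE)
  expect_equal(c(st$valence, st$arousal), c(1, 0))
  # streaming trajectories clamp; tabular trajectories reject
  traj <- affect_trajectory(function(bar) c(1.5, 0.5))
  expect_equal(state_at(traj, 1)$valence, 1)
  expect_error(affect_trajectory(data.frame(valence = 1.5, arousal = 0.5)),
               "outside")
})

test_that("tempo is affine in arousal with endpoints 60 and 200 bpm", {
  expect_equal(tempo_from_arousal(affect_state(0.5, 0)), 60)
  expect_equal(tempo_from_arousal(affect_state(0.5, 1)), 200)
  expect_equal(tempo_from_arousal(affect_state(0.5, 0.5)), 130)
  a <- seq(0, 1, by = 0.05)
  tempos <- vapply(a, function(x) tempo_from_arousal(affect_state(0, x)), 0)
  expect_true(all(diff(tempos) > 0))
  expect_equal(tempos, 60 + 140 * a)
})

test_that("velocity range has width 30 and the printed endpoints", {
  expect_equal(unname(velocity_range(affect_state(0, 0))), c(40, 70))
  expect_equal(unname(velocity_range(affect_state(0, 1))), c(85, 115))
  expect_equal(unname(velocity_range(affect_state(0, 0.5))), c(62.5, 92.5))
  for (a in seq(0, 1, by = 0.1)) {
    r <- velocity_range(affect_state(0.3, a))
    expect_equal(unname(diff(r)), 30)
  }
})

test_that("bar velocity respects the range and the per-bar change cap", {
  set.seed(11)
  first <- replicate(500, sample_bar_velocity(affect_state(0, 0)))
  expect_true(all(first >= 40 & first <= 70))
  # previous 70, arousal 0, cap 6: intersection [64, 70]
  v <- replicate(500, sample_bar_velocity(affect_state(0, 0), 70))
  expect_true(all(v >= 64 & v <= 70))
  # previous 100, arousal 1, cap 25: intersection is the full range [85, 115]
  v <- replicate(500, sample_bar_velocity(affect_state(0, 1), 100))
  expect_true(all(v >= 85 & v <= 115))
  # empty intersection snaps to the nearest endpoint of the permissible range
  expect_equal(sample_bar_velocity(affect_state(0, 0), 120), 70)
  expect_equal(sample_bar_velocity(affect_state(0, 0), 10), 40)
})

test_that("valence regions partition [0,1] into 10 half-open bins", {
  expect_equal(valence_region(affect_state(0, 0)), 0L)
  expect_equal(valence_region(affect_state(1, 0)), 9L)
  expect_equal(valence_region(affect_state(0.25, 0)), 2L)
  eps <- 1e-9
  for (k in 0:9) {
    lo <- k / 10
    expect_equal(valence_region(affect_state(lo, 0)), k)
    expect_equal(valence_region(affect_state(lo + 0.1 - eps, 0)), k)
  }
  v <- runif(200)
  regions <- vapply(v, function(x) valence_region(affect_state(x, 0)), 0L)
  expect_true(all(regions == pmin(floor(v * 10), 9)))
})

test_that("register bounds interpolate between [C1,C5] and [G3,C6] monotonically", {
  expect_equal(unname(register_bounds(affect_state(0.05, 0))), c(24L, 72L))
  expect_equal(unname(register_bounds(affect_state(0.95, 0))), c(55L, 84L))
  expect_equal(unname(register_bounds(affect_state(0.55, 0))), c(41L, 79L))
  tab <- t(vapply(0:9, function(k)
    register_bounds(affect_state(k / 10 + 0.05, 0)), integer(2)))
  expect_true(all(diff(tab[, 1]) >= 0))
  expect_true(all(diff(tab[, 2]) >= 0))
})

test_that("arousal rhythm and melody regions use the documented boundaries", {
  reg <- function(a) arousal_rhythm_region(affect_state(0, a))
  expect_equal(reg(0.39), "low")
  expect_equal(reg(0.4), "moderate")
  expect_equal(reg(0.75), "moderate")
  expect_equal(reg(0.76), "high")
  mel <- function(a) arousal_melody_region(affect_state(0, a))
  expect_equal(c(mel(0), mel(0.49), mel(0.5), mel(1)), c(0L, 0L, 1L, 1L))
})

test_that("roughness falls linearly with arousal down to the 0.3 floor", {
  r <- function(a) roughness_from_arousal(affect_state(0, a))
  expect_equal(r(0), 1)
  expect_equal(r(1), 0.3)
  expect_equal(r(0.7), 0.3)
  expect_equal(r(0.4), 0.6)
  vals <- vapply(seq(0, 1, by = 0.05), r, 0)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0.3))
})

test_that("each mapping depends only on its documented affect dimension", {
  grid <- expand.grid(v = seq(0, 1, by = 0.25), a = seq(0, 1, by = 0.25))
  for (a in unique(grid$a)) {
    sts <- lapply(unique(grid$v), function(v) affect_state(v, a))
    # arousal-driven mappings ignore valence
    expect_length(unique(vapply(sts, tempo_from_arousal, 0)), 1L)
    expect_length(unique(vapply(sts, function(s) velocity_range(s)[[1]], 0)), 1L)
    expect_length(unique(vapply(sts, arousal_rhythm_region, "")), 1L)
    expect_length(unique(vapply(sts, arousal_melody_region, 0L)), 1L)
    expect_length(unique(vapply(sts, roughness_from_arousal, 0)), 1L)
  }
  for (v in unique(grid$v)) {
    sts <- lapply(unique(grid$a), function(a) affect_state(v, a))
    # valence-driven mappings ignore arousal
    expect_length(unique(vapply(sts, valence_region, 0L)), 1L)
    expect_length(unique(vapply(sts, function(s)
      paste(register_bounds(s), collapse = ","), "")), 1L)
  }
})
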