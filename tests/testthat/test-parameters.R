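# Spatio-temporal parameters and side summaries.

test_that("phase durations in %GC are run fractions times 100", {
  runs <- data.frame(phase = c("H", "F", "P", "S"),
                     duration_s = c(0.10, 0.25, 0.25, 0.40))
  expect_equal(phase_durations_pct(runs),
               c(H = 10, F = 25, P = 25, S = 40))
  eq <- data.frame(phase = c("H", "F", "P", "S"), duration_s = rep(0.3, 4))
  expect_equal(unname(phase_durations_pct(eq)), rep(25, 4))
  atyp <- data.frame(phase = c("P", "S"), duration_s = c(0.5, 0.5))
  expect_error(phase_durations_pct(atyp), "typical")
})

test_that("cadence is cycles per minute over the observation time", {
  expect_equal(cadence(269, 300), 53.8)
  expect_equal(cadence(0, 300), 0)
  expect_equal(cadence(100, 600), cadence(100, 300) / 2)
  expect_error(cadence(10, 0), "positive")
})

test_that("double support matches a constructed overlap oracle", {
  # 1-s cycles; left stance [0, 0.56); right swing [0.12, 0.56) lies inside
  # the left stance, so bilateral contact is 0.12 of every left cycle
  lphases <- c("S", rep(c("H", "F", "P", "S"), 4))
  ldurs <- c(0.20, rep(c(0.10, 0.20, 0.26, 0.44), 4))
  rphases <- c("S", rep(c("P", "S", "H", "F", "P"), 4))
  rdurs <- c(0.20, rep(c(0.12, 0.44, 0.10, 0.20, 0.14), 4))
  left <- phase_signal_from(lphases, ldurs)
  right <- phase_signal_from(rphases, rdurs)
  stopifnot(length(left$labels) == length(right$labels))
  cyc <- segment_cycles(left)
  expect_equal(double_support_pct(left, right, cyc, mode = "total"), 12,
               tolerance = 1e-9)
  expect_equal(double_support_pct(left, right, cyc, mode = "initial"), 12,
               tolerance = 1e-9)
})

test_that("alternating contact gives zero double support", {
  left <- phase_signal_from(rep(c("S", "P"), 6), rep(0.5, 12))
  right <- phase_signal_from(rep(c("P", "S"), 6), rep(0.5, 12))
  cyc <- segment_cycles(left)
  expect_equal(double_support_pct(left, right, cyc), 0)
})

test_that("a permanently loaded contralateral side gives stance-level double support", {
  lphases <- c("S", rep(c("H", "F", "P", "S"), 3))
  ldurs <- c(0.2, rep(c(0.1, 0.2, 0.26, 0.44), 3))
  left <- phase_signal_from(lphases, ldurs)
  right <- phase_signal_from("F", sum(ldurs))
  cyc <- segment_cycles(left)
  expect_equal(double_support_pct(left, right, cyc), 56, tolerance = 1e-9)
})

test_that("double support requires a shared time base", {
  a <- phase_signal_from(c("S", "H", "S"), c(0.5, 0.5, 0.5), fs = 100)
  b <- phase_signal_from(c("S", "H", "S"), c(0.5, 0.5, 0.5), fs = 200)
  expect_error(double_support_pct(a, b, segment_cycles(a)), "time base")
})

test_that("walking speed pools distance and time over passages", {
  iv <- data.frame(start_s = c(0, 9, 11, 20), end_s = c(9, 11, 20, 22),
                   label = c("straight", "turn", "straight", "turn"))
  one <- annotation_track(iv, data.frame(start_s = 0, end_s = 9))
  expect_equal(walking_speed(one), 1.0)
  two <- annotation_track(iv, data.frame(start_s = c(0, 11), end_s = c(9, 20)))
  expect_equal(walking_speed(two), 1.0)
  fast <- annotation_track(data.frame(start_s = 0, end_s = 8.33, label = "straight"),
                           data.frame(start_s = 0, end_s = 8.33))
  expect_equal(walking_speed(fast), 9 / 8.33)
  expect_error(walking_speed(annotation_track(iv)), "no timed passages")
})

test_that("Atyp divides the atypical percentage by speed", {
  expect_equal(atyp_normalized(20, 1.0), 20)
  expect_equal(atyp_normalized(20, 2.0), 10)
  expect_equal(atyp_normalized(25.4, 1.01), 25.1, tolerance = 0.05)
  expect_error(atyp_normalized(20, 0), "positive")
})

test_that("side summary percentages are consistent and additive", {
  # 10 cycles: 8 typical, 1 atypical in the straight region, 1 in the turn
  phases <- c("S")
  durs <- c(0.2)
  classes <- c(rep("HFPS", 4), "PS", rep("HFPS", 4), "PFPS", "HFPS")
  for (cl in classes) {
    letters_ <- strsplit(cl, "")[[1]]
    phases <- c(phases, letters_)
    durs <- c(durs, rep(0.8 / length(letters_), length(letters_)))
  }
  sig <- phase_signal_from(phases, durs)
  # cycle onsets every 0.8 s from 0.2 s; put the PS cycle (5th) in a turn
  turn_start <- 3.4
  track <- annotation_track(data.frame(
    start_s = c(0, turn_start, turn_start + 0.8),
    end_s = c(turn_start, turn_start + 0.8, 20),
    label = c("straight", "turn", "straight")))
  cyc <- tag_regions(segment_cycles(sig), track)
  s <- summarize_side(cyc, recording_duration_s = sum(durs), track = track)
  expect_equal(s$n_cycles, 10)
  expect_equal(s$pct_typical + s$pct_atypical, 100)
  expect_equal(s$pct_atypical, 20)
  expect_equal(unname(s$region_atypical_pct[c("straight", "turn")]), c(10, 10))
  expect_equal(sum(s$region_atypical_pct), s$pct_atypical)
  expect_equal(sum(s$class_pct), s$pct_atypical)
  expect_equal(sum(s$phase_pct), 100, tolerance = 1e-6)
})

test_that("an all-typical side has full typical percentage and no classes", {
  phases <- c("S", rep(c("H", "F", "P", "S"), 5))
  durs <- c(0.2, rep(0.2, 20))
  s <- summarize_side(segment_cycles(phase_signal_from(phases, durs)),
                      recording_duration_s = sum(durs))
  expect_equal(s$pct_typical, 100)
  expect_length(s$class_pct, 0)
})

test_that("zero cycles produce a flagged empty summary", {
  s <- summarize_side(segment_cycles(phase_signal_from("S", 3)),
                      recording_duration_s = 3)
  expect_true(s$empty)
  expect_equal(s$n_cycles, 0)
  expect_true(is.na(s$pct_atypical))
})

test_that("straight-only cadence uses straight cycles over straight time", {
  phases <- c("S", rep(c("H", "F", "P", "S"), 6))
  durs <- c(0.2, rep(0.25, 24))
  track <- annotation_track(data.frame(
    start_s = c(0, 4), end_s = c(4, 10), label = c("straight", "turn")))
  cyc <- tag_regions(segment_cycles(phase_signal_from(phases, durs)), track)
  s_all <- summarize_side(cyc, 6.2, track = track, cadence_mode = "all")
  s_str <- summarize_side(cyc, 6.2, track = track, cadence_mode = "straight")
  expect_equal(s_all$cadence, nrow(cyc) / (6.2 / 60))
  expect_equal(s_str$cadence, sum(cyc$region == "straight") / (4 / 60))
})
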