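# Gait-cycle segmentation, classification and region tagging.

test_that("hand-traced segmentation of S H F P S H F P S H gives two HFPS cycles", {
  phases <- c("S", "H", "F", "P", "S", "H", "F", "P", "S", "H")
  sig <- phase_signal_from(phases, rep(0.2, length(phases)))
  cyc <- segment_cycles(sig)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$class_label, c("HFPS", "HFPS"))
  expect_true(all(cyc$is_typical))
  # onsets at each S -> H transition (0.2 s runs)
  expect_equal(cyc$start_s, c(0.2, 1.0))
  expect_equal(cyc$end_s, c(1.0, 1.8))
  # run durations partition the cycle exactly
  for (i in 1:2)
    expect_equal(sum(cyc$phase_runs[[i]]$duration_s), cyc$duration_s[i])
})

test_that("constant swing yields no cycles", {
  sig <- phase_signal_from("S", 2)
  expect_equal(nrow(segment_cycles(sig)), 0)
})

test_that("a forefoot strike opens a cycle at the S -> P transition", {
  phases <- c("S", "P", "S", "H", "F", "P", "S", "H")
  sig <- phase_signal_from(phases, rep(0.2, length(phases)))
  cyc <- segment_cycles(sig)
  expect_equal(cyc$class_label, c("PS", "HFPS"))
  expect_equal(cyc$is_typical, c(FALSE, TRUE))
})

test_that("classification is open-vocabulary: typical iff exactly HFPS", {
  expect_true(classify_cycle("HFPS")$is_typical)
  for (lab in c("PFPS", "PS", "FPS", "HFHFPS", "HS", "HFS", "HFPHPS"))
    expect_false(classify_cycle(lab)$is_typical)
})

test_that("typical + atypical counts partition the segmented cycles", {
  phases <- c("S", "H", "F", "P", "S", "P", "F", "P", "S", "H", "F", "P", "S", "H")
  sig <- phase_signal_from(phases, rep(0.15, length(phases)))
  cyc <- segment_cycles(sig)
  expect_equal(sum(cyc$is_typical) + sum(!cyc$is_typical), nrow(cyc))
  expect_equal(cyc$class_label[2], "PFPS")
})

test_that("segmentation is invariant to swing padding at either end", {
  phases <- c("S", "H", "F", "P", "S", "H", "F", "P", "S", "H")
  durs <- rep(0.2, length(phases))
  base <- segment_cycles(phase_signal_from(phases, durs))
  padded <- segment_cycles(phase_signal_from(c("S", phases, "S"), c(1, durs, 1.5)))
  expect_equal(padded$class_label, base$class_label)
  expect_equal(padded$duration_s, base$duration_s)
  expect_equal(padded$start_s, base$start_s + 1)
})

test_that("over-long segments are discarded as pauses but logged", {
  phases <- c("S", "H", "F", "P", "S", "H", "F", "P", "S", "H")
  durs <- c(0.2, 0.2, 0.2, 0.2, 4.0, 0.2, 0.2, 0.2, 0.2, 0.2)
  cyc <- segment_cycles(phase_signal_from(phases, durs), max_cycle_s = 3)
  expect_equal(nrow(cyc), 1)              # the 4.8 s segment is dropped
  expect_equal(attr(cyc, "n_discarded"), 1)
  expect_equal(nrow(attr(cyc, "discarded")), 1)
  expect_gt(attr(cyc, "discarded")$duration_s[1], 3)
})

test_that("cycles are tagged by the interval containing their onset", {
  track <- annotation_track(
    data.frame(start_s = c(0, 9), end_s = c(9, 11),
               label = c("straight", "turn")))
  phases <- c("S", "H", "F", "P", "S", "H", "F", "P", "S", "H")
  # first onset at 4.0 s, second at 9.5 s
  durs <- c(4.0, 1.5, 1.5, 1.5, 1.0, 0.4, 0.4, 0.4, 0.4, 0.5)
  sig <- phase_signal_from(phases, durs, fs = 100)
  cyc <- tag_regions(segment_cycles(sig, max_cycle_s = 10), track)
  expect_equal(cyc$region, c("straight", "turn"))
  # onset outside every interval -> unknown
  track2 <- annotation_track(
    data.frame(start_s = 5, end_s = 6, label = "turn"))
  cyc2 <- tag_regions(segment_cycles(sig, max_cycle_s = 10), track2)
  expect_equal(cyc2$region, c("unknown", "unknown"))
})
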