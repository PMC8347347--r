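# Synthetic cohort generator: determinism, truth-table consistency,
# class-rate recovery, noise behaviour.

test_that("the same seed reproduces byte-identical cohort files", {
  cfg <- test_cfg(n_pd = 1, n_control = 1, minutes = 0.4, fs = 100,
                  bounce = 0.5, seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("generated channels obey the phase truth table exactly without bounce", {
  cfg <- test_cfg(n_pd = 1, n_control = 0, minutes = 0.5, fs = 100,
                  bounce = 0, seed = 32)
  co <- simulate_cohort(cfg)
  sub <- co$subjects$pd01
  # raw encoding (no cleaning passes) must already segment into exactly the
  # injected classes: the channels realise the intended phases per sample
  sig <- encode_phases(sub$left, min_phase_s = 0)
  cyc <- segment_cycles(sig)
  tr <- sub$truth[sub$truth$side == "left" & sub$truth$complete, ]
  expect_equal(cyc$class_label, tr$class_label)
  expect_equal(cyc$start_s, tr$start_s, tolerance = 1e-9)
})

test_that("injected class shares are recovered within exact binomial bounds", {
  # fix the atypical probability at 0.25 in both regions, all atypicals PS
  draft <- test_cfg(n_pd = 1, n_control = 0, minutes = 3, fs = 100, seed = 1)
  f_t <- footsga:::expected_turn_fraction(draft, "PD")
  rates <- default_atypical_rates()
  rates[, "straight"] <- 25 * (1 - f_t)
  rates[, "turn"] <- 25 * f_t
  mix <- default_class_mix()
  mix[] <- 0; mix[, "PS"] <- 1
  cfg <- test_cfg(n_pd = 1, n_control = 0, minutes = 3, fs = 100, bounce = 0,
                  seed = 33, atypical_rates = rates, class_mix = mix,
                  pd_affected_frac = 0, severity_sdlog = c(PD = 1e-6, control = 1e-6))
  co <- simulate_cohort(cfg)
  tr <- co$truth_cycles[co$truth_cycles$side == "left" & co$truth_cycles$complete, ]
  n <- nrow(tr)
  expect_gt(n, 120)
  k <- sum(tr$class_label == "PS")
  expect_true(all(tr$class_label %in% c("HFPS", "PS")))
  # exact binomial 99% interval around 0.25
  expect_gte(k, qbinom(0.005, n, 0.25))
  expect_lte(k, qbinom(0.995, n, 0.25))
  # and the pipeline recovers the identical share
  res <- analyze_subject(co$subjects$pd01$left, co$subjects$pd01$right,
                         co$subjects$pd01$annotations)
  rec <- cycle_table(res)
  expect_equal(sum(rec$class_label[rec$side == "left"] == "PS"), k)
})

test_that("sub-threshold bounce is fully removed: end-to-end class recovery", {
  cfg <- test_cfg(n_pd = 1, n_control = 1, minutes = 0.6, fs = 500,
                  bounce = 1.0, seed = 34)
  co <- simulate_cohort(cfg)
  for (id in names(co$subjects)) {
    sub <- co$subjects[[id]]
    res <- analyze_subject(sub$left, sub$right, sub$annotations)
    rec <- cycle_table(res)
    for (side in c("left", "right")) {
      tr <- sub$truth[sub$truth$side == side & sub$truth$complete, ]
      expect_equal(rec$class_label[rec$side == side], tr$class_label,
                   label = paste(id, side))
    }
  }
})

test_that("recovery error of the atypical rate shrinks with the cycle count", {
  rates <- default_atypical_rates()
  draft <- test_cfg(n_pd = 1, n_control = 0, minutes = 1, fs = 100, seed = 1)
  f_t <- footsga:::expected_turn_fraction(draft, "PD")
  rates[, "straight"] <- 25 * (1 - f_t)
  rates[, "turn"] <- 25 * f_t
  mae <- vapply(c(0.5, 4), function(minutes) {
    cfg <- test_cfg(n_pd = 4, n_control = 0, minutes = minutes, fs = 100,
                    bounce = 0, seed = 35, atypical_rates = rates,
                    pd_affected_frac = 0,
                    severity_sdlog = c(PD = 1e-6, control = 1e-6))
    co <- simulate_cohort(cfg)
    mean(abs(co$truth_subjects$pct_atypical - 25))
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("turn cycles are attributed to turn intervals in the schedule", {
  cfg <- test_cfg(n_pd = 1, n_control = 0, minutes = 1, fs = 100,
                  bounce = 0, seed = 36)
  co <- simulate_cohort(cfg)
  tr <- co$truth_cycles
  expect_true(all(tr$region %in% c("straight", "turn")))
  expect_gt(sum(tr$region == "turn"), 0)
  # the annotated turn time fraction is near the configured model
  iv <- co$subjects$pd01$annotations$intervals
  frac <- sum((iv$end_s - iv$start_s)[iv$label == "turn"]) / sum(iv$end_s - iv$start_s)
  expect_gt(frac, 0.1); expect_lt(frac, 0.45)
})

test_that("a degenerate cohort request errors", {
  expect_error(simulate_cohort(test_cfg(n_pd = 0, n_control = 0, seed = 1)),
               "empty cohort")
})

test_that("the motor-score link responds to severity and respects b = 0", {
  cfg <- test_cfg(seed = 1)
  set.seed(37)
  atyp <- c(5, 10, 30, 60)
  aff <- c(0, 0, 1, 1)
  u <- simulate_updrs(atyp, aff, cfg)
  expect_true(all(u >= 0))
  expect_true(all(u == round(u)))
  # flat link: scores do not depend on Atyp
  cfg0 <- test_cfg(seed = 1, updrs_slope = 0,
                   updrs_noise_sd = c(affected = 4, unaffected = 4))
  set.seed(38)
  u0 <- simulate_updrs(rep(c(0, 100), each = 2000), rep(0, 4000), cfg0)
  expect_lt(abs(mean(u0[1:2000]) - mean(u0[2001:4000])), 0.5)
})
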