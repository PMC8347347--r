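# Synthetic cohort generator.  Emulates the acquisition protocol the
# analysis assumes: approximately five-minute barefoot walks back and forth
# over a 9-m straight path, bilateral heel/met1/met5 switch channels sampled
# at 2 kHz, manual straight/turn annotation and timed straight passages, a
# case-control cohort with side roles, and a motor score linked to the
# speed-normalised atypical-cycle percentage.  Every random draw is governed
# by the cohort seed, and the generator emits a ground-truth table for every
# injected cycle.

#' Reference per-side gait parameter profiles
#'
#' Published cohort summary profiles used as the generator defaults:
#' mean phase durations in %GC for typical cycles (`default_phase_profiles`),
#' overall atypical-cycle percentages per walking-path region
#' (`default_atypical_rates`, % of all cycles of the side), and the mixture
#' of atypical classes (`default_class_mix`, proportions among atypical
#' cycles; the PFPS and PS columns follow the published class prevalences,
#' the remainder is split over FPS, HFHFPS and an open "other" category).
#' Rows are the four group-side cells: PD more-/less-affected side, control
#' dominant/non-dominant side.
#'
#' @return A numeric matrix with one row per group-side cell.
#' @export
default_phase_profiles <- function() {
  m <- rbind(
    PD.more_affected     = c(H = 9.6, F = 20.3, P = 25.5, S = 44.6),
    PD.less_affected     = c(H = 9.1, F = 22.2, P = 24.7, S = 44.0),
    control.dominant     = c(H = 7.1, F = 25.0, P = 24.4, S = 43.4),
    control.non_dominant = c(H = 9.9, F = 24.9, P = 22.8, S = 42.3))
  m
}

#' @rdname default_phase_profiles
#' @export
default_atypical_rates <- function() {
  rbind(
    PD.more_affected     = c(straight = 12.3, turn = 13.1),
    PD.less_affected     = c(straight = 4.8,  turn = 10.7),
    control.dominant     = c(straight = 2.0,  turn = 6.1),
    control.non_dominant = c(straight = 2.5,  turn = 6.3))
}

#' @rdname default_phase_profiles
#' @export
default_class_mix <- function() {
  tot <- c(25.4, 15.5, 8.1, 8.8)
  pfps <- c(6.7, 5.8, 3.7, 2.7) / tot
  ps <- c(6.1, 2.0, 0.4, 1.1) / tot
  rest <- 1 - pfps - ps
  m <- cbind(PFPS = pfps, PS = ps, FPS = 0.40 * rest,
             HFHFPS = 0.35 * rest, other = 0.25 * rest)
  rownames(m) <- rownames(default_atypical_rates())
  m
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults encode the emulated study conditions: 20 patients and 20
#' controls, five-minute walks at 2 kHz over a 9-m path, group speed and
#' cadence models, per-cell typical phase profiles, per-cell and per-region
#' atypical rates, and the motor-score link.  Between-subject heterogeneity
#' of atypical rates uses a two-component severity model: a fraction
#' `pd_affected_frac` of patients is "gait-affected" (logit offset
#' `affected_delta` on the atypical odds); within components, per-side
#' severities are log-normal on the odds scale (`severity_sdlog`) with
#' between-side correlation `severity_side_cor`.  The motor score is flat at
#' `updrs_intercept` below `updrs_knee` (in Atyp units) and rises with slope
#' `updrs_slope` above it, with Gaussian noise `updrs_noise_sd` (affected /
#' unaffected); setting `updrs_knee = 0` and equal noise gives a plain
#' linear link.
#'
#' @param n_pd,n_control Group sizes.
#' @param recording_minutes Walk duration in minutes.
#' @param sampling_rate Sampling rate in Hz.
#' @param path_length_m Straight-path length in metres.
#' @param turn_duration_s,turn_jitter_s U-turn duration model (seconds).
#' @param turn_stride_factor Turning strides are this fraction of the
#'   straight stride period (turning uses shorter, quicker steps).
#' @param speed Named list of `c(mean, sd)` walking-speed models (m/s) per
#'   group.
#' @param stride_period Named list of `c(mean, sd)` per-subject stride
#'   period models (s) per group.
#' @param stride_jitter_s Within-subject cycle-to-cycle SD of the stride
#'   period (s).
#' @param phase_profile,atypical_rates,class_mix See
#'   [default_phase_profiles()].
#' @param pd_affected_frac,affected_delta,severity_sdlog,severity_side_cor
#'   Severity model (see Details above).
#' @param phase_conc Dirichlet concentration for cycle-to-cycle jitter of
#'   the phase fractions.
#' @param subject_phase_conc Named per-group Dirichlet concentrations for
#'   the between-subject variation of the stance split (H/F/P shares;
#'   lower = more heterogeneous; patients are more heterogeneous than
#'   controls).
#' @param subject_swing_conc Concentration for the between-subject
#'   variation of the swing fraction, which is much more stable across
#'   subjects than the stance split.
#' @param min_phase_s Minimum realised phase-run duration (s).
#' @param bounce_rate_hz Spurious switch toggles per second per channel.
#' @param bounce_max_s Maximum bounce duration (s); keep below the debounce
#'   threshold so that filtering removes all injected bounce.
#' @param updrs_intercept,updrs_slope,updrs_knee,updrs_noise_sd Motor-score
#'   link (noise SD is `c(affected, unaffected)`).
#' @param more_affected_right_frac,dominant_right_frac Fraction of subjects
#'   whose more-affected (dominant) side is the right one.
#' @param lead_in_s Swing-only lead-in before the first contact onset (s).
#' @param seed Integer seed fixing the whole cohort.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    n_pd = 20, n_control = 20,
    recording_minutes = 5, sampling_rate = 2000, path_length_m = 9,
    turn_duration_s = 2.5, turn_jitter_s = 0.25, turn_stride_factor = 0.75,
    speed = list(PD = c(mean = 1.01, sd = 0.25),
                 control = c(mean = 1.08, sd = 0.17)),
    stride_period = list(PD = c(mean = 60 / 55.7, sd = 0.114),
                         control = c(mean = 60 / 54.6, sd = 0.066)),
    stride_jitter_s = 0.03,
    phase_profile = default_phase_profiles(),
    atypical_rates = default_atypical_rates(),
    class_mix = default_class_mix(),
    pd_affected_frac = 0.5, affected_delta = 2.4,
    severity_sdlog = c(PD = 0.5, control = 1.5),
    severity_side_cor = 0.4,
    phase_conc = 300, subject_phase_conc = c(PD = 50, control = 150),
    subject_swing_conc = 400, min_phase_s = 0.05,
    bounce_rate_hz = 0.2, bounce_max_s = 0.012,
    updrs_intercept = 13, updrs_slope = 0.4, updrs_knee = 15,
    updrs_noise_sd = c(affected = 2.5, unaffected = 8),
    more_affected_right_frac = 9 / 20, dominant_right_frac = 18 / 20,
    lead_in_s = 0.4,
    seed = NULL) {
  cfg <- list(n_pd = n_pd, n_control = n_control,
              recording_minutes = recording_minutes,
              sampling_rate = sampling_rate, path_length_m = path_length_m,
              turn_duration_s = turn_duration_s, turn_jitter_s = turn_jitter_s,
              turn_stride_factor = turn_stride_factor,
              speed = speed, stride_period = stride_period,
              stride_jitter_s = stride_jitter_s,
              phase_profile = phase_profile, atypical_rates = atypical_rates,
              class_mix = class_mix,
              pd_affected_frac = pd_affected_frac, affected_delta = affected_delta,
              severity_sdlog = severity_sdlog,
              severity_side_cor = severity_side_cor,
              phase_conc = phase_conc, subject_phase_conc = subject_phase_conc,
              subject_swing_conc = subject_swing_conc,
              min_phase_s = min_phase_s,
              bounce_rate_hz = bounce_rate_hz, bounce_max_s = bounce_max_s,
              updrs_intercept = updrs_intercept, updrs_slope = updrs_slope,
              updrs_knee = updrs_knee, updrs_noise_sd = updrs_noise_sd,
              more_affected_right_frac = more_affected_right_frac,
              dominant_right_frac = dominant_right_frac,
              lead_in_s = lead_in_s, seed = seed)
  stopifnot(cfg$sampling_rate > 0, cfg$recording_minutes > 0,
            cfg$path_length_m > 0, all(cfg$atypical_rates >= 0),
            cfg$pd_affected_frac >= 0, cfg$pd_affected_frac <= 1,
            all(abs(rowSums(cfg$class_mix) - 1) < 1e-8),
            cfg$bounce_max_s >= 0, cfg$min_phase_s > 0)
  cfg$cell_logits <- calibrate_cell_logits(cfg)
  structure(cfg, class = "synth_config")
}

# ---- severity calibration --------------------------------------------------

# E[plogis(l0 + offset)] under the mixture severity model, by midpoint
# quadrature over the log-normal component.
severity_mean_p <- function(l0, sdlog, pi_aff, delta) {
  z <- qnorm((seq_len(801) - 0.5) / 801)
  base <- sdlog * z - sdlog^2 / 2
  pi_aff * mean(plogis(l0 + delta + base)) +
    (1 - pi_aff) * mean(plogis(l0 + base))
}

# Solve for the base logit that gives each cell/region its target
# conditional atypical probability in expectation over severity.
calibrate_cell_logits <- function(cfg) {
  cells <- rownames(cfg$atypical_rates)
  out <- matrix(NA_real_, length(cells), 2,
                dimnames = list(cells, c("straight", "turn")))
  for (cell in cells) {
    group <- sub("\\..*$", "", cell)
    f_turn <- expected_turn_fraction(cfg, group)
    cond <- c(straight = cfg$atypical_rates[cell, "straight"] / 100 / (1 - f_turn),
              turn = cfg$atypical_rates[cell, "turn"] / 100 / f_turn)
    if (any(cond >= 1))
      stop("atypical-rate targets infeasible for the configured turn fraction")
    sl <- cfg$severity_sdlog[[group]]
    pi_aff <- if (group == "PD") cfg$pd_affected_frac else 0
    delta <- if (group == "PD") cfg$affected_delta else 0
    for (rg in c("straight", "turn")) {
      if (cond[[rg]] <= 0) { out[cell, rg] <- -Inf; next }
      out[cell, rg] <- uniroot(function(l0)
        severity_mean_p(l0, sl, pi_aff, delta) - cond[[rg]],
        c(-25, 25))$root
    }
  }
  out
}

# Expected fraction of gait cycles falling in U-turns, from the group mean
# speed and stride period and the turn model.
expected_turn_fraction <- function(cfg, group) {
  speed <- cfg$speed[[group]][["mean"]]
  stride <- cfg$stride_period[[group]][["mean"]]
  cyc_straight <- (cfg$path_length_m / speed) / stride
  cyc_turn <- cfg$turn_duration_s / (stride * cfg$turn_stride_factor)
  cyc_turn / (cyc_turn + cyc_straight)
}

# ---- per-subject generation ------------------------------------------------

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  for (i in which(x <= lower)) {
    for (try in 1:100) {
      x[i] <- rnorm(1, mean, sd)
      if (x[i] > lower) break
    }
    if (x[i] <= lower) x[i] <- lower + abs(x[i] - lower) / 2 + 1e-3
  }
  x
}

# Alternating straight/turn schedule covering the recording.
make_schedule <- function(cfg, speed, total_s) {
  straight_d <- cfg$path_length_m / speed
  start <- numeric(0); end <- numeric(0); label <- character(0)
  t <- 0; is_straight <- TRUE
  while (t < total_s) {
    d <- if (is_straight) straight_d else
      max(1, rnorm(1, cfg$turn_duration_s, cfg$turn_jitter_s))
    start <- c(start, t); end <- c(end, min(t + d, total_s))
    label <- c(label, if (is_straight) "straight" else "turn")
    t <- t + d
    is_straight <- !is_straight
  }
  data.frame(start_s = start, end_s = end, label = label,
             stringsAsFactors = FALSE)
}

schedule_region <- function(schedule, t) {
  i <- findInterval(t, schedule$start_s)
  i <- pmin(pmax(i, 1L), nrow(schedule))
  schedule$label[i]
}

# A random legal contact sequence different from HFPS: contact letters drawn
# from {H, F, P} without immediate repeats, closed by a final swing.
random_other_class <- function() {
  repeat {
    len <- sample(1:5, 1)
    letters_ <- character(len)
    pool <- c("H", "F", "P")
    letters_[1] <- sample(pool, 1)
    if (len > 1)
      for (i in 2:len) letters_[i] <- sample(setdiff(pool, letters_[i - 1]), 1)
    lab <- paste(c(letters_, "S"), collapse = "")
    if (lab != "HFPS") return(lab)
  }
}

# Distribute the cycle among the letters of a class string: swing keeps its
# base fraction; the stance mass is shared by the stance letters
# proportionally to their base fractions (repeated letters split equally).
realize_class_fractions <- function(class_label, base_frac, min_frac) {
  letters_ <- strsplit(class_label, "")[[1]]
  k <- length(letters_)
  stance <- letters_[-k]                      # final letter is S
  w <- base_frac[stance] / as.numeric(table(stance)[stance])
  frac <- c(unname(base_frac["S"]), unname(w / sum(w)) * (1 - base_frac["S"]))
  frac <- c(frac[-1], frac[1])                # stance runs then swing
  frac <- pmax(frac, min_frac)
  frac / sum(frac)
}

# Fill the switch channels of one realised cycle; returns nothing, mutates
# the channel vectors in the caller's environment for speed.
write_cycle_runs <- function(env, start_idx, n_samp, letters_, frac, min_samp) {
  counts <- pmax(min_samp, round(frac * n_samp))
  excess <- sum(counts) - n_samp
  k <- length(counts)
  counts[k] <- counts[k] - excess             # swing absorbs rounding
  if (counts[k] < min_samp)
    stop("infeasible phase profile: cycle too short for its phase runs")
  at <- start_idx
  for (i in seq_len(k)) {
    idx <- at:(at + counts[i] - 1L)
    ph <- letters_[i]
    if (ph == "H") {
      env$heel[idx] <- 1L
    } else if (ph == "F" || ph == "P") {
      if (ph == "F") env$heel[idx] <- 1L
      pat <- sample.int(3L, 1L, prob = c(0.4, 0.3, 0.3))
      if (pat == 1L || pat == 3L) env$met1[idx] <- 1L
      if (pat == 2L || pat == 3L) env$met5[idx] <- 1L
    }                                          # S: all open
    at <- at + counts[i]
  }
  invisible(NULL)
}

inject_bounce <- function(ch, fs, rate_hz, max_s) {
  n <- length(ch)
  n_ev <- rpois(1, rate_hz * n / fs)
  if (!n_ev) return(ch)
  margin <- max(2L, round(0.2 * fs))
  if (n_ev > n - 2L * margin) n_ev <- n - 2L * margin
  # bounce events are isolated toggles: enforce a separation of several
  # maximal bounce durations so that two events can never fuse into a run
  # at or above the debounce threshold
  min_gap <- round(3 * max_s * fs) + 2L
  pos <- sort(sample.int(n - 2L * margin, n_ev) + margin)
  pos <- pos[c(TRUE, diff(pos) > min_gap)]
  for (p in pos) {
    dur <- max(1L, round(runif(1, 0.002, max_s) * fs))
    idx <- p:min(p + dur - 1L, n - margin)
    ch[idx] <- 1L - ch[idx]
  }
  ch
}

# Realise one side of a subject: channels + per-cycle truth.
realize_side <- function(cfg, side, role_cell, onsets_s, classes, regions,
                         n_samples, fs) {
  env <- new.env()
  env$heel <- integer(n_samples)
  env$met1 <- integer(n_samples)
  env$met5 <- integer(n_samples)
  cell_frac <- cfg$phase_profile[role_cell, ] / sum(cfg$phase_profile[role_cell, ])
  # subjects differ in their habitual profile around the cell mean: the
  # swing fraction is tightly conserved, the stance split much less so
  conc_split <- cfg$subject_phase_conc[[sub("\\..*$", "", role_cell)]]
  gs <- rgamma(1, shape = cfg$subject_swing_conc * cell_frac[["S"]])
  gc_ <- rgamma(1, shape = cfg$subject_swing_conc * (1 - cell_frac[["S"]]))
  s_frac <- gs / (gs + gc_)
  split <- rgamma(3, shape = conc_split * cell_frac[c("H", "F", "P")] /
                    (1 - cell_frac[["S"]]))
  base_frac <- setNames(c((1 - s_frac) * split / sum(split), s_frac),
                        c("H", "F", "P", "S"))
  min_samp <- max(1L, ceiling(cfg$min_phase_s * fs))
  n_cyc <- length(onsets_s) - 1L
  for (k in seq_len(n_cyc)) {
    start_idx <- round(onsets_s[k] * fs) + 1L
    end_idx <- round(onsets_s[k + 1L] * fs)
    n_samp <- end_idx - start_idx + 1L
    jit <- rgamma(4, shape = cfg$phase_conc * base_frac)
    frac0 <- setNames(jit / sum(jit), names(base_frac))
    letters_ <- strsplit(classes[k], "")[[1]]
    min_frac <- min_samp / n_samp
    frac <- realize_class_fractions(classes[k], frac0, min_frac)
    write_cycle_runs(env, start_idx, n_samp, letters_, frac, min_samp)
  }
  if (cfg$bounce_rate_hz > 0) {
    env$heel <- inject_bounce(env$heel, fs, cfg$bounce_rate_hz, cfg$bounce_max_s)
    env$met1 <- inject_bounce(env$met1, fs, cfg$bounce_rate_hz, cfg$bounce_max_s)
    env$met5 <- inject_bounce(env$met5, fs, cfg$bounce_rate_hz, cfg$bounce_max_s)
  }
  truth <- data.frame(
    side = side, cycle = seq_len(n_cyc),
    start_s = (round(onsets_s[-length(onsets_s)] * fs)) / fs,
    end_s = (round(onsets_s[-1L] * fs)) / fs,
    class_label = classes[seq_len(n_cyc)],
    is_typical = classes[seq_len(n_cyc)] == "HFPS",
    region = regions[seq_len(n_cyc)],
    stringsAsFactors = FALSE)
  list(channels = list(heel = env$heel, met1 = env$met1, met5 = env$met5),
       truth = truth)
}

#' Generate one synthetic subject
#'
#' Draws the subject-level quantities (speed, stride period, severity,
#' gait-affection state), lays out the straight/turn schedule, realises the
#' per-cycle classes and phase runs on both sides (the right side is
#' phase-locked half a stride after the left, which produces physiological
#' double support), reconstructs switch channels satisfying the phase truth
#' table at every sample, and optionally injects sub-threshold switch
#' bounce.  Uses the current RNG state; seed via [simulate_cohort()] or
#' `set.seed()`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Identifier.
#' @param group `"PD"` or `"control"`.
#' @param affected_side The more-affected (PD) or dominant (control) side.
#' @return A list with elements `left` and `right`
#'   ([switch_recording()]s), `annotations` ([annotation_track()]), `truth`
#'   (per-cycle data frame with a `complete` flag; the last cycle of a side
#'   has no closing onset and is not recoverable by segmentation), `speed`
#'   (true walking speed), `gait_affected`, and `roles` (side-to-role map).
#' @export
simulate_subject <- function(cfg, subject_id, group = c("PD", "control"),
                             affected_side = c("right", "left")) {
  stopifnot(inherits(cfg, "synth_config"))
  group <- match.arg(group)
  affected_side <- match.arg(affected_side)
  fs <- cfg$sampling_rate
  total_s <- cfg$recording_minutes * 60
  n_samples <- round(total_s * fs)

  speed <- rtrunc_norm(1, cfg$speed[[group]][["mean"]],
                       cfg$speed[[group]][["sd"]], lower = 0.4)
  stride <- rtrunc_norm(1, cfg$stride_period[[group]][["mean"]],
                        cfg$stride_period[[group]][["sd"]], lower = 0.7)
  gait_affected <- if (group == "PD") rbinom(1, 1, cfg$pd_affected_frac) else 0L
  sdlog <- cfg$severity_sdlog[[group]]
  rho <- cfg$severity_side_cor
  z_sub <- rnorm(1)
  log_sev <- vapply(c("left", "right"), function(s) {
    z <- sqrt(rho) * z_sub + sqrt(1 - rho) * rnorm(1)
    sdlog * z - sdlog^2 / 2 + (if (group == "PD") cfg$affected_delta * gait_affected else 0)
  }, numeric(1))

  schedule <- make_schedule(cfg, speed, total_s)

  roles <- side_roles(group, affected_side)
  role_cell <- paste(group, roles, sep = ".")
  names(role_cell) <- names(roles)

  # left-side onset schedule; right side phase-locked half a stride later
  draw_onsets <- function(start_t) {
    t <- start_t; onsets <- numeric(0); periods <- numeric(0)
    repeat {
      region <- schedule_region(schedule, t)
      p <- stride * (if (region == "turn") cfg$turn_stride_factor else 1) +
        rnorm(1, 0, cfg$stride_jitter_s)
      p <- max(0.5 * stride * cfg$turn_stride_factor, p)
      if (t + p > total_s - 1 / fs) break
      onsets <- c(onsets, t); periods <- c(periods, p)
      t <- t + p
    }
    list(onsets = c(onsets, t), periods = periods)   # last entry closes cycles
  }
  left_sched <- draw_onsets(cfg$lead_in_s)
  onsets_l <- left_sched$onsets
  onsets_r <- head(onsets_l, -1L) + left_sched$periods / 2 + rnorm(length(left_sched$periods), 0, 0.01)
  dr <- pmax(0.4 * stride * cfg$turn_stride_factor, diff(onsets_r))
  onsets_r <- onsets_r[1L] + c(0, cumsum(dr))
  onsets_r <- onsets_r[onsets_r <= total_s - 1 / fs]

  draw_cycle_marks <- function(onsets, side) {
    n_cyc <- length(onsets) - 1L
    if (n_cyc < 1L) return(list(classes = character(0), regions = character(0)))
    regions <- schedule_region(schedule, onsets[seq_len(n_cyc)])
    logits <- cfg$cell_logits[role_cell[[side]], ]
    p_atyp <- plogis(logits[regions] + log_sev[[side]])
    classes <- vapply(seq_len(n_cyc), function(k) {
      if (runif(1) >= p_atyp[k]) return("HFPS")
      cls <- sample(colnames(cfg$class_mix), 1,
                    prob = cfg$class_mix[role_cell[[side]], ])
      if (cls == "other") random_other_class() else cls
    }, character(1))
    list(classes = classes, regions = regions)
  }

  sides <- list()
  truth <- NULL
  for (side in c("left", "right")) {
    onsets <- if (side == "left") onsets_l else onsets_r
    marks <- draw_cycle_marks(onsets, side)
    real <- realize_side(cfg, side, role_cell[[side]], onsets, marks$classes,
                         marks$regions, n_samples, fs)
    sides[[side]] <- switch_recording(subject_id, side, fs,
                                      real$channels$heel, real$channels$met1,
                                      real$channels$met5)
    tr <- real$truth
    if (nrow(tr)) {
      tr$role <- roles[[side]]
      # the final realised cycle has no closing contact onset in the signal
      # (the recording ends in swing), so segmentation cannot recover it
      tr$complete <- c(rep(TRUE, nrow(tr) - 1L), FALSE)
    }
    truth <- rbind(truth, tr)
  }

  straight <- schedule[schedule$label == "straight", , drop = FALSE]
  full <- straight$end_s - straight$start_s >= cfg$path_length_m / speed - 1e-9
  track <- annotation_track(
    intervals = schedule[, c("start_s", "end_s", "label")],
    passages = straight[full, c("start_s", "end_s")],
    path_length_m = cfg$path_length_m)

  list(left = sides$left, right = sides$right, annotations = track,
       truth = cbind(subject_id = subject_id, truth),
       speed = speed, gait_affected = gait_affected, roles = roles)
}

#' Side-to-role mapping
#'
#' @param group `"PD"` or `"control"`.
#' @param affected_side The more-affected (PD) or dominant (control) side.
#' @return Named character vector mapping `left`/`right` to roles.
#' @export
side_roles <- function(group, affected_side) {
  if (group == "PD") {
    r <- c(left = "less_affected", right = "less_affected")
    r[affected_side] <- "more_affected"
  } else {
    r <- c(left = "non_dominant", right = "non_dominant")
    r[affected_side] <- "dominant"
  }
  r
}

#' Motor score from the speed-normalised atypical percentage
#'
#' Threshold-linear link: below `updrs_knee` the expected score is flat at
#' `updrs_intercept` (the score is then dominated by non-gait symptoms,
#' which is also why the score noise is larger for gait-unaffected
#' patients); above the knee it rises with `updrs_slope` per Atyp unit.
#' Gaussian noise is added and the score floored at zero and rounded to an
#' integer, as clinical scores are.
#'
#' @param atyp True Atyp values (% per m/s).
#' @param gait_affected 0/1 vector: draws noise SD
#'   `updrs_noise_sd["affected"]` vs `["unaffected"]`.
#' @param cfg A [synth_config()].
#' @return Integer scores.
#' @export
simulate_updrs <- function(atyp, gait_affected, cfg) {
  sd_vec <- ifelse(gait_affected == 1, cfg$updrs_noise_sd[["affected"]],
                   cfg$updrs_noise_sd[["unaffected"]])
  u <- cfg$updrs_intercept + cfg$updrs_slope * pmax(atyp - cfg$updrs_knee, 0) +
    rnorm(length(atyp), 0, sd_vec)
  pmax(0, round(u))
}

#' Generate a full synthetic cohort
#'
#' Draws `n_pd + n_control` subjects with side-role assignment (a
#' configurable fraction of patients more-affected on the right, of controls
#' right-dominant), simulates each subject's bilateral recording, computes
#' the per-subject ground-truth atypical statistics and the linked motor
#' score, and optionally writes everything to disk in the CSV formats the
#' readers understand (`<id>_left.csv`, `<id>_right.csv`,
#' `<id>_annotations.csv`, `metadata.csv`, `truth_cycles.csv`,
#' `truth_subjects.csv`).
#'
#' @param cfg A [synth_config()]; its `seed` fixes the full output.
#' @param out_dir Optional output directory.
#' @return A list of class `synth_cohort`: `subjects` (named list of
#'   [simulate_subject()] results), `meta` (metadata data frame with
#'   `updrs3`), `truth_cycles` (all injected cycles) and `truth_subjects`
#'   (per subject-side true summary: `n_cycles`, `pct_atypical`,
#'   `straight_atypical_pct`, `turn_atypical_pct`, plus `speed` and
#'   `atyp_true`).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_pd + cfg$n_control == 0) stop("empty cohort requested")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  ids <- c(sprintf("pd%02d", seq_len(cfg$n_pd)),
           sprintf("ct%02d", seq_len(cfg$n_control)))
  groups <- rep(c("PD", "control"), c(cfg$n_pd, cfg$n_control))
  right_aff <- c(sample(rep(c("right", "left"),
                            c(round(cfg$more_affected_right_frac * cfg$n_pd),
                              cfg$n_pd - round(cfg$more_affected_right_frac * cfg$n_pd)))),
                 sample(rep(c("right", "left"),
                            c(round(cfg$dominant_right_frac * cfg$n_control),
                              cfg$n_control - round(cfg$dominant_right_frac * cfg$n_control)))))

  subjects <- list()
  truth_cycles <- NULL
  rows <- list()
  for (i in seq_along(ids)) {
    sub <- simulate_subject(cfg, ids[i], groups[i], right_aff[i])
    subjects[[ids[i]]] <- sub
    truth_cycles <- rbind(truth_cycles, sub$truth)
    tc <- sub$truth[sub$truth$complete, , drop = FALSE]
    for (side in c("left", "right")) {
      d <- tc[tc$side == side, , drop = FALSE]
      n <- nrow(d)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], side = side,
        role = sub$roles[[side]], n_cycles = n,
        pct_atypical = if (n) 100 * sum(!d$is_typical) / n else NA_real_,
        straight_atypical_pct = if (n) 100 * sum(!d$is_typical & d$region == "straight") / n else NA_real_,
        turn_atypical_pct = if (n) 100 * sum(!d$is_typical & d$region == "turn") / n else NA_real_,
        speed = sub$speed, gait_affected = sub$gait_affected,
        stringsAsFactors = FALSE)
    }
  }
  truth_subjects <- do.call(rbind, rows)
  truth_subjects$atyp_true <- truth_subjects$pct_atypical / truth_subjects$speed

  # motor score from the more-affected-side truth
  meta <- data.frame(subject_id = ids, group = groups,
                     affected_side = right_aff, stringsAsFactors = FALSE)
  more <- truth_subjects[truth_subjects$role %in% c("more_affected", "dominant"), ]
  more <- more[match(ids, more$subject_id), ]
  updrs <- rep(NA_real_, length(ids))
  is_pd <- groups == "PD"
  updrs[is_pd] <- simulate_updrs(more$atyp_true[is_pd],
                                 more$gait_affected[is_pd], cfg)
  meta$updrs3 <- updrs
  meta$hoehn_yahr <- ifelse(is_pd, pmax(1, round(rnorm(length(ids), 1.7, 0.4) * 2) / 2), NA)

  cohort <- structure(list(subjects = subjects, meta = meta,
                           truth_cycles = truth_cycles,
                           truth_subjects = truth_subjects, config = cfg),
                      class = "synth_cohort")
  if (!is.null(out_dir)) write_cohort_files(cohort, out_dir)
  cohort
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d PD + %d control subjects, %g min @ %g Hz (seed %s)\n",
              x$config$n_pd, x$config$n_control, x$config$recording_minutes,
              x$config$sampling_rate,
              if (is.null(x$config$seed)) "none" else x$config$seed))
  invisible(x)
}

write_cohort_files <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    write_switch_csv(sub$left, file.path(out_dir, paste0(id, "_left.csv")))
    write_switch_csv(sub$right, file.path(out_dir, paste0(id, "_right.csv")))
    write_annotations(sub$annotations,
                      file.path(out_dir, paste0(id, "_annotations.csv")))
  }
  write_subject_meta(cohort$meta, file.path(out_dir, "metadata.csv"))
  write.csv(cohort$truth_cycles, file.path(out_dir, "truth_cycles.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$truth_subjects, file.path(out_dir, "truth_subjects.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
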