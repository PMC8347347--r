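# Test helpers: independent oracles and small signal builders.

# Independent debounce oracle: recompute the run-length encoding of the
# whole vector on every pass and overwrite the earliest shortest interior
# sub-threshold run with the value of the preceding sample, until a
# fixpoint.  Deliberately written against the raw vector (not the rle
# bookkeeping of the implementation under test).
oracle_debounce <- function(x, min_len) {
  repeat {
    r <- rle(x)
    k <- length(r$lengths)
    if (k <= 2L) return(x)
    idx <- which(r$lengths < min_len - 1e-9)
    idx <- idx[idx > 1L & idx < k]
    if (!length(idx)) return(x)
    i <- idx[order(r$lengths[idx], idx)][1L]
    start <- sum(r$lengths[seq_len(i - 1L)]) + 1L
    x[start:(start + r$lengths[i] - 1L)] <- x[start - 1L]
  }
}

# Random binary signal with geometric run lengths (realistic block structure).
random_block_signal <- function(n, mean_run = 8) {
  v <- integer(0)
  val <- sample(0:1, 1)
  while (length(v) < n) {
    len <- 1L + stats::rgeom(1, 1 / mean_run)
    v <- c(v, rep(val, len))
    val <- 1L - val
  }
  v[seq_len(n)]
}

# Build a switch recording realising a given phase sequence with given run
# durations (seconds).  Phases map to canonical switch states (F and P use
# met1 only).
rec_from_phases <- function(phases, durations_s, fs = 100,
                            subject = "t1", side = "left") {
  states <- list(H = c(1L, 0L, 0L), F = c(1L, 1L, 0L),
                 P = c(0L, 1L, 0L), S = c(0L, 0L, 0L))
  heel <- met1 <- met5 <- integer(0)
  for (i in seq_along(phases)) {
    n <- round(durations_s[i] * fs)
    st <- states[[phases[i]]]
    heel <- c(heel, rep(st[1], n))
    met1 <- c(met1, rep(st[2], n))
    met5 <- c(met5, rep(st[3], n))
  }
  switch_recording(subject, side, fs, heel, met1, met5)
}

phase_signal_from <- function(phases, durations_s, fs = 100) {
  encode_phases(rec_from_phases(phases, durations_s, fs), min_phase_s = 0)
}

# Small scaled-down generator configuration used across tests: the study's
# rates and cohort structure at reduced sampling rate and duration.
test_cfg <- function(n_pd = 20, n_control = 20, minutes = 1.5, fs = 100,
                     bounce = 0, seed = NULL, ...) {
  synth_config(n_pd = n_pd, n_control = n_control,
               recording_minutes = minutes, sampling_rate = fs,
               bounce_rate_hz = bounce, seed = seed, ...)
}
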