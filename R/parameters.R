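# Per-subject, per-side spatio-temporal parameters and atypical-cycle
# statistics.

#' Gait-phase durations as percentage of the gait cycle
#'
#' For a typical (`HFPS`) cycle, returns the duration of each phase divided
#' by the cycle duration, times 100.  The four values sum to 100 exactly.
#' Atypical cycles have no canonical H/F/P/S decomposition and are rejected;
#' callers filter on `is_typical` first.
#'
#' @param phase_runs A per-cycle `(phase, duration_s)` data frame, or one
#'   row of a `gait_cycles` object.
#' @return Named numeric vector `c(H=, F=, P=, S=)` in %GC.
#' @export
phase_durations_pct <- function(phase_runs) {
  if (is.data.frame(phase_runs) && "phase_runs" %in% names(phase_runs))
    phase_runs <- phase_runs$phase_runs[[1L]]
  if (paste(phase_runs$phase, collapse = "") != "HFPS")
    stop("phase durations in %GC are defined for typical (HFPS) cycles only")
  pct <- 100 * phase_runs$duration_s / sum(phase_runs$duration_s)
  setNames(pct, phase_runs$phase)
}

#' Cadence in gait cycles per minute
#'
#' @param n_cycles Number of gait cycles counted.
#' @param duration_s Observation time in seconds over which they were
#'   counted.
#' @return Cadence in cycles/min.
#' @export
cadence <- function(n_cycles, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  n_cycles / (duration_s / 60)
}

#' Double support as percentage of the gait cycle
#'
#' Double support is the part of the cycle during which both feet are on
#' the floor (neither side in swing).  For each cycle of the reference side
#' the fraction of samples with bilateral contact is computed and averaged
#' over cycles.  The default `"total"` mode counts both double-support
#' periods of the cycle; `"initial"` counts only the period that starts at
#' the cycle's contact onset.
#'
#' @param sig A `phase_signal` for the reference side.
#' @param other_sig The contralateral `phase_signal`; must share the time
#'   base (same sampling rate and length).
#' @param cycles `gait_cycles` of the reference side.
#' @param mode `"total"` or `"initial"`.
#' @return Mean double support in %GC (`NA` if there are no cycles).
#' @export
double_support_pct <- function(sig, other_sig, cycles, mode = c("total", "initial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sig, "phase_signal"), inherits(other_sig, "phase_signal"))
  if (sig$sampling_rate != other_sig$sampling_rate ||
      length(sig$labels) != length(other_sig$labels))
    stop("the two phase signals do not share a time base")
  if (!nrow(cycles)) return(NA_real_)
  fs <- sig$sampling_rate
  both <- sig$labels != "S" & other_sig$labels != "S"
  per_cycle <- vapply(seq_len(nrow(cycles)), function(i) {
    i0 <- round(cycles$start_s[i] * fs) + 1L
    i1 <- round(cycles$end_s[i] * fs)
    idx <- both[i0:i1]
    if (mode == "total") {
      mean(idx)
    } else {
      # length of the TRUE run beginning at the onset sample
      if (!idx[1L]) 0 else {
        off <- which(!idx)
        (if (length(off)) off[1L] - 1L else length(idx)) / length(idx)
      }
    }
  }, numeric(1))
  100 * mean(per_cycle)
}

#' Self-selected walking speed from timed passages
#'
#' The total distance walked along the straight path divided by the total
#' time spent in the timed passages: with k passages of a path of length L,
#' speed = k * L / sum of passage durations.  Pooling distance and time
#' (rather than averaging per-passage speeds) matches stopwatch timing of
#' repeated passages.
#'
#' @param track An [annotation_track()] with at least one timed passage.
#' @return Speed in m/s.
#' @export
walking_speed <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  k <- nrow(track$passages)
  if (!k) stop("no timed passages: walking speed undefined")
  k * track$path_length_m / sum(track$passages$end_s - track$passages$start_s)
}

#' Speed-normalised atypical-cycle percentage (Atyp)
#'
#' Normalising the percentage of atypical gait cycles by the self-selected
#' walking speed makes the parameter comparable across subjects walking at
#' different speeds: `Atyp = pct_atypical / speed`.
#'
#' @param pct_atypical Percentage of atypical cycles (0-100).
#' @param speed_m_s Walking speed in m/s (positive).
#' @return Atyp, in % per (m/s).
#' @export
atyp_normalized <- function(pct_atypical, speed_m_s) {
  if (any(speed_m_s <= 0)) stop("`speed_m_s` must be positive")
  pct_atypical / speed_m_s
}

#' Summarise the gait cycles of one side
#'
#' Aggregates segmented, classified and region-tagged cycles of one
#' body side into the side-level statistics: counts, typical/atypical
#' percentages, per-class percentages, straight/turn atypical percentages,
#' mean phase durations (%GC, typical cycles only) and cadence.  All
#' percentages use the total number of cycles of the side (turns included)
#' as denominator, so straight + turn atypical percentages add up to the
#' total atypical percentage whenever every onset is covered by an
#' annotation interval.
#'
#' @param cycles A region-tagged `gait_cycles` data frame.
#' @param recording_duration_s Duration of the recording in seconds
#'   (cadence denominator in `"all"` mode).
#' @param track Optional [annotation_track()]; required for
#'   `cadence_mode = "straight"`.
#' @param cadence_mode `"all"` (cycles over the whole recording, default) or
#'   `"straight"` (straight-walk cycles over total straight time).
#' @return An object of class `side_summary`: list with `n_cycles`,
#'   `pct_typical`, `pct_atypical`, `phase_pct` (named H/F/P/S means),
#'   `class_pct` (named percentage per atypical class), `region_atypical_pct`
#'   (named `straight`/`turn`/`unknown`), `cadence`, `cadence_mode` and
#'   `n_discarded`.  With zero cycles the percentages are `NA` and the
#'   summary is flagged `empty = TRUE`.
#' @export
summarize_side <- function(cycles, recording_duration_s, track = NULL,
                           cadence_mode = c("all", "straight")) {
  cadence_mode <- match.arg(cadence_mode)
  stopifnot(inherits(cycles, "gait_cycles"))
  n <- nrow(cycles)
  if (!n) {
    return(structure(list(
      n_cycles = 0L, pct_typical = NA_real_, pct_atypical = NA_real_,
      phase_pct = setNames(rep(NA_real_, 4), c("H", "F", "P", "S")),
      class_pct = numeric(0),
      region_atypical_pct = c(straight = NA_real_, turn = NA_real_, unknown = NA_real_),
      cadence = 0, cadence_mode = cadence_mode,
      n_discarded = attr(cycles, "n_discarded"), empty = TRUE),
      class = "side_summary"))
  }
  atyp <- !cycles$is_typical
  class_tab <- table(cycles$class_label[atyp])
  region <- factor(cycles$region, levels = c("straight", "turn", "unknown"))
  region_tab <- table(region[atyp])
  typ_runs <- cycles$phase_runs[cycles$is_typical]
  phase_pct <- if (length(typ_runs)) {
    m <- vapply(typ_runs, phase_durations_pct, numeric(4))
    rowMeans(m)
  } else setNames(rep(NA_real_, 4), c("H", "F", "P", "S"))

  cad <- if (cadence_mode == "all") {
    cadence(n, recording_duration_s)
  } else {
    if (is.null(track)) stop("straight-only cadence needs an annotation track")
    straight <- track$intervals[track$intervals$label == "straight", , drop = FALSE]
    t_straight <- sum(straight$end_s - straight$start_s)
    cadence(sum(cycles$region == "straight"), t_straight)
  }
  structure(list(
    n_cycles = n,
    pct_typical = 100 * sum(cycles$is_typical) / n,
    pct_atypical = 100 * sum(atyp) / n,
    phase_pct = phase_pct,
    class_pct = setNames(100 * as.numeric(class_tab) / n, names(class_tab)),
    region_atypical_pct = setNames(100 * as.numeric(region_tab) / n, names(region_tab)),
    cadence = cad, cadence_mode = cadence_mode,
    n_discarded = attr(cycles, "n_discarded"), empty = FALSE),
    class = "side_summary")
}

#' @export
print.side_summary <- function(x, ...) {
  cat(sprintf("<side_summary> %d cycles: %.1f%% typical, %.1f%% atypical; cadence %.1f cycles/min (%s)\n",
              x$n_cycles, x$pct_typical, x$pct_atypical, x$cadence, x$cadence_mode))
  if (!x$empty)
    cat(sprintf("  phase %%GC (typical): H %.1f, F %.1f, P %.1f, S %.1f | atypical by region: straight %.1f, turn %.1f\n",
                x$phase_pct["H"], x$phase_pct["F"], x$phase_pct["P"], x$phase_pct["S"],
                x$region_atypical_pct["straight"], x$region_atypical_pct["turn"]))
  invisible(x)
}
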