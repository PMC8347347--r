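# On-disk artifacts: switch signals, annotation tracks, cohort metadata,
# result tables.  All formats are plain CSV; times are seconds from the
# start of the recording and intervals are half-open [start, end).

#' Construct a foot-switch recording
#'
#' A recording holds the three binary switch channels of one body side,
#' sampled at a fixed rate: `heel`, `met1` (first metatarsal head) and
#' `met5` (fifth metatarsal head).  A closed switch (foot segment on the
#' floor) reads 1, an open switch 0.
#'
#' @param subject_id Subject identifier.
#' @param side `"left"` or `"right"`.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param heel,met1,met5 Equal-length binary (0/1) sample vectors.
#' @return An object of class `switch_recording`.
#' @export
switch_recording <- function(subject_id, side, sampling_rate, heel, met1, met5) {
  side <- match.arg(side, c("left", "right"))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  n <- length(heel)
  if (length(met1) != n || length(met5) != n)
    stop("heel, met1 and met5 must have the same length")
  if (n == 0L) stop("recording must contain at least one sample")
  for (ch in list(heel, met1, met5))
    if (!all(ch %in% c(0, 1))) stop("switch channels must be binary (0/1)")
  structure(
    list(subject_id = as.character(subject_id), side = side,
         sampling_rate = sampling_rate,
         heel = as.integer(heel), met1 = as.integer(met1), met5 = as.integer(met5)),
    class = "switch_recording")
}

#' @export
print.switch_recording <- function(x, ...) {
  cat(sprintf("<switch_recording> subject %s, %s side: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$side, length(x$heel), x$sampling_rate,
              recording_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec A `switch_recording`.
#' @return Duration in seconds (`n_samples / sampling_rate`).
#' @export
recording_duration <- function(rec) length(rec$heel) / rec$sampling_rate

#' Read a foot-switch recording from CSV
#'
#' The file must have columns `time_s`, `heel`, `met1`, `met5` with a
#' monotone time column at a fixed step.  The sampling rate is inferred from
#' the median time step; any step deviating from it by more than 1% is a
#' format error, as is any non-binary channel value.
#'
#' @param path Path to the CSV file.
#' @param subject_id,side Identity of the recording; defaults are parsed
#'   from the file name (`<subject>_<side>.csv`) when possible.
#' @return A [switch_recording()].
#' @export
read_switch_csv <- function(path, subject_id = NULL, side = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "heel", "met1", "met5")
  if (!all(need %in% names(df)))
    stop("switch CSV must have columns time_s, heel, met1, met5")
  if (nrow(df) < 2L) stop("switch CSV must contain at least two samples")
  dt <- diff(df$time_s)
  step <- median(dt)
  if (step <= 0 || any(dt <= 0))
    stop("time_s must be strictly increasing")
  if (any(abs(dt - step) > 0.01 * step))
    stop("irregular time step in switch CSV (beyond 1% tolerance)")
  for (ch in need[-1])
    if (!all(df[[ch]] %in% c(0, 1)))
      stop(sprintf("non-binary values in channel '%s'", ch))
  if (is.null(subject_id) || is.null(side)) {
    base <- sub("\\.csv$", "", basename(path))
    guess_side <- if (grepl("right$", base)) "right" else "left"
    if (is.null(side)) side <- guess_side
    if (is.null(subject_id)) subject_id <- sub("_(left|right)$", "", base)
  }
  switch_recording(subject_id, side, 1 / step, df$heel, df$met1, df$met5)
}

#' Write a foot-switch recording to CSV
#'
#' @param rec A [switch_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_switch_csv <- function(rec, path) {
  stopifnot(inherits(rec, "switch_recording"))
  n <- length(rec$heel)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$sampling_rate,
                   heel = rec$heel, met1 = rec$met1, met5 = rec$met5)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an annotation track
#'
#' An annotation track partitions the walk into straight-walking and U-turn
#' intervals and lists the manually timed straight passages with a known
#' path length, from which the self-selected walking speed is computed.
#'
#' @param intervals Data frame with columns `start_s`, `end_s`, `label`
#'   (`"straight"` or `"turn"`); intervals are half-open and must not
#'   overlap.
#' @param passages Data frame with columns `start_s`, `end_s`: timed
#'   straight passages.  Every passage must lie within a straight interval.
#' @param path_length_m Length in metres of the straight path covered by
#'   each timed passage.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(intervals = NULL, passages = NULL, path_length_m = 9) {
  if (is.null(intervals))
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            label = character(0), stringsAsFactors = FALSE)
  if (is.null(passages))
    passages <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (!is.numeric(path_length_m) || path_length_m <= 0)
    stop("`path_length_m` must be positive")
  if (nrow(intervals)) {
    if (!all(intervals$label %in% c("straight", "turn")))
      stop("interval labels must be 'straight' or 'turn'")
    if (any(intervals$start_s >= intervals$end_s))
      stop("intervals must satisfy start < end")
    o <- order(intervals$start_s)
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)]))
      stop("annotation intervals overlap")
    rownames(intervals) <- NULL
  }
  if (nrow(passages)) {
    if (any(passages$start_s >= passages$end_s))
      stop("passages must satisfy start < end")
    straight <- intervals[intervals$label == "straight", , drop = FALSE]
    inside <- vapply(seq_len(nrow(passages)), function(i) {
      any(straight$start_s <= passages$start_s[i] &
            passages$end_s[i] <= straight$end_s)
    }, logical(1))
    if (!all(inside))
      stop("every timed passage must lie within a straight interval")
    passages <- passages[order(passages$start_s), c("start_s", "end_s"), drop = FALSE]
    rownames(passages) <- NULL
  }
  structure(list(intervals = intervals, passages = passages,
                 path_length_m = path_length_m),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d intervals (%d straight, %d turn), %d timed passages, path %g m\n",
              nrow(x$intervals), sum(x$intervals$label == "straight"),
              sum(x$intervals$label == "turn"), nrow(x$passages),
              x$path_length_m))
  invisible(x)
}

#' Read an annotation track from CSV
#'
#' Rows are `(start_s, end_s, label)` with labels `straight`, `turn` or
#' `passage`.  Straight/turn rows form the region partition; `passage` rows
#' are the manually timed straight passages.  An empty file yields an empty
#' track (all cycle regions then come out `"unknown"`).
#'
#' @param path Path to the CSV file.
#' @param path_length_m Straight-path length in metres (not stored in the
#'   CSV; part of the acquisition protocol).
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, path_length_m = 9) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(annotation_track(path_length_m = path_length_m))
  if (!all(c("start_s", "end_s", "label") %in% names(df)))
    stop("annotation CSV must have columns start_s, end_s, label")
  if (!all(df$label %in% c("straight", "turn", "passage")))
    stop("unknown annotation label(s): ",
         paste(setdiff(unique(df$label), c("straight", "turn", "passage")),
               collapse = ", "))
  annotation_track(
    intervals = df[df$label != "passage", c("start_s", "end_s", "label")],
    passages = df[df$label == "passage", c("start_s", "end_s")],
    path_length_m = path_length_m)
}

#' Write an annotation track to CSV
#'
#' @param track An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  df <- rbind(track$intervals,
              if (nrow(track$passages))
                data.frame(track$passages, label = "passage"))
  df <- df[order(df$start_s, df$label), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from CSV
#'
#' Expected columns: `subject_id`, `group` (`PD` or `control`),
#' `affected_side` (`left`/`right`; the more-affected side for PD subjects,
#' the dominant side for controls), `updrs3` (motor score; `NA` for
#' controls) and optionally `hoehn_yahr`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per subject.
#' @export
read_subject_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "affected_side")
  if (!all(need %in% names(df)))
    stop("metadata CSV must have columns subject_id, group, affected_side")
  if (!all(df$group %in% c("PD", "control")))
    stop("group must be 'PD' or 'control'")
  if (!all(df$affected_side %in% c("left", "right")))
    stop("affected_side must be 'left' or 'right'")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in metadata")
  if (!"updrs3" %in% names(df)) df$updrs3 <- NA_real_
  df
}

#' Write cohort metadata to CSV
#'
#' @param meta Data frame as returned by [read_subject_meta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_meta <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cohort summary tables to CSV
#'
#' Writes the two cohort tables produced by [cohort_report()]: the
#' spatio-temporal/typicality table (one row per gait parameter, mean and SD
#' per group-side cell, ANOVA or two-group p-values) and the per-region
#' atypical-cycle table (straight walking and U-turning rows).  A third file
#' collects the full test battery (method, statistic, p, effect size).
#'
#' @param report A `cohort_report` object from [cohort_report()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_cohort_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  if (!nrow(report$table1)) stop("empty cohort: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(out_dir, "cohort_parameters.csv"),
             file.path(out_dir, "cohort_region_atypical.csv"),
             file.path(out_dir, "cohort_stat_tests.csv"))
  write.csv(fmt_table(report$table1), files[1], row.names = FALSE, quote = FALSE)
  write.csv(fmt_table(report$table2), files[2], row.names = FALSE, quote = FALSE)
  write.csv(report$tests, files[3], row.names = FALSE, quote = FALSE)
  invisible(files)
}

# round numeric columns for the printed tables (1 decimal, p to 4)
fmt_table <- function(df) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    df[[nm]] <- round(df[[nm]], if (grepl("^p_", nm)) 4L else 1L)
  }
  df
}

#' Read back a cohort summary table
#'
#' @param path Path to a CSV written by [write_cohort_tables()].
#' @return A data frame.
#' @export
read_cohort_table <- function(path) read.csv(path, stringsAsFactors = FALSE)
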