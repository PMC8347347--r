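# Segmentation of the phase signal into gait cycles and classification of
# each cycle by its foot-floor contact sequence.

#' Segment a phase signal into gait cycles
#'
#' A gait cycle runs from one contact onset (a transition from swing `S`
#' into any contact phase) to the next contact onset of the same foot.
#' Opening cycles at any contact onset, not only at heel strike, is required
#' to capture cycles with forefoot initial contact (`PFPS`, `PS`) or
#' flat-foot initial contact (`FPS`).  Partial segments before the first
#' onset and after the last onset are discarded.  Segments longer than
#' `max_cycle_s` are treated as pauses: they are excluded from the returned
#' cycles and reported in the `"discarded"` attribute rather than silently
#' dropped.
#'
#' @param sig A `phase_signal` from [encode_phases()].
#' @param max_cycle_s Sanity threshold in seconds above which a segment is
#'   considered a pause rather than a gait cycle.
#' @return A data frame of class `gait_cycles` with columns `start_s`,
#'   `end_s`, `duration_s`, `class_label` (run-length phase sequence),
#'   `is_typical` (`TRUE` iff the sequence is exactly `HFPS`), `region`
#'   (initially `"unknown"`; see [tag_regions()]) and a list column
#'   `phase_runs` of per-cycle `(phase, duration_s)` data frames.
#'   Attributes: `sampling_rate`, `n_discarded`, `discarded`.
#' @export
segment_cycles <- function(sig, max_cycle_s = 3) {
  stopifnot(inherits(sig, "phase_signal"))
  if (!length(sig$labels)) stop("empty phase signal")
  fs <- sig$sampling_rate
  r <- rle(sig$labels)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  prev <- c(NA_character_, r$values[-length(r$values)])
  onset <- which(r$values != "S" & !is.na(prev) & prev == "S")

  empty <- empty_cycles(fs)
  if (length(onset) < 2L) return(empty)

  rows <- lapply(seq_len(length(onset) - 1L), function(i) {
    from <- onset[i]
    to <- onset[i + 1L] - 1L
    runs <- data.frame(phase = r$values[from:to],
                       duration_s = r$lengths[from:to] / fs,
                       stringsAsFactors = FALSE)
    start_s <- (run_start[from] - 1L) / fs
    end_s <- (run_start[onset[i + 1L]] - 1L) / fs
    list(start_s = start_s, end_s = end_s,
         class_label = paste(runs$phase, collapse = ""), runs = runs)
  })
  cyc <- data.frame(
    start_s = vapply(rows, `[[`, numeric(1), "start_s"),
    end_s = vapply(rows, `[[`, numeric(1), "end_s"),
    stringsAsFactors = FALSE)
  cyc$duration_s <- cyc$end_s - cyc$start_s
  cyc$class_label <- vapply(rows, `[[`, character(1), "class_label")
  cyc$is_typical <- classify_sequence(cyc$class_label)
  cyc$region <- "unknown"
  cyc$phase_runs <- I(lapply(rows, `[[`, "runs"))

  keep <- cyc$duration_s <= max_cycle_s
  out <- cyc[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("gait_cycles", "data.frame"),
            sampling_rate = fs,
            n_discarded = sum(!keep),
            discarded = cyc[!keep, c("start_s", "end_s", "duration_s", "class_label")])
}

empty_cycles <- function(fs) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    duration_s = numeric(0), class_label = character(0),
                    is_typical = logical(0), region = character(0),
                    stringsAsFactors = FALSE)
  out$phase_runs <- I(list())
  structure(out, class = c("gait_cycles", "data.frame"),
            sampling_rate = fs, n_discarded = 0L,
            discarded = out[, c("start_s", "end_s", "duration_s", "class_label")])
}

#' Classify a gait cycle by its contact sequence
#'
#' The physiological foot-floor contact sequence is heel contact, flat-foot
#' contact, push-off, swing (`HFPS`); any other sequence is atypical, e.g.
#' `PFPS` and `PS` (forefoot initial contact), `FPS` (flat-foot initial
#' contact) or `HFHFPS` (unstable heel contact).  The class label is the
#' run-length-encoded phase string itself, so the classifier has an open
#' vocabulary.
#'
#' @param class_label Character vector of run-length phase sequences.
#' @return `classify_sequence()` returns a logical vector (`TRUE` =
#'   typical).  `classify_cycle()` returns a list with `is_typical` and
#'   `class_label` for a single sequence.
#' @export
classify_sequence <- function(class_label) class_label == "HFPS"

#' @rdname classify_sequence
#' @export
classify_cycle <- function(class_label) {
  stopifnot(is.character(class_label), length(class_label) == 1L)
  list(is_typical = classify_sequence(class_label), class_label = class_label)
}

#' Attribute gait cycles to walking-path regions
#'
#' Each cycle is tagged by the annotation interval containing its contact
#' onset (`start_s`); a cycle whose onset falls outside every interval is
#' tagged `"unknown"`.  Tagging by onset rather than majority overlap is
#' deterministic and matches per-cycle counting of region statistics.
#'
#' @param cycles A `gait_cycles` data frame from [segment_cycles()].
#' @param track An [annotation_track()].
#' @return `cycles` with the `region` column filled in.
#' @export
tag_regions <- function(cycles, track) {
  stopifnot(inherits(cycles, "gait_cycles"), inherits(track, "annotation_track"))
  if (!nrow(cycles)) return(cycles)
  region <- rep("unknown", nrow(cycles))
  iv <- track$intervals
  for (j in seq_len(nrow(iv))) {
    hit <- cycles$start_s >= iv$start_s[j] & cycles$start_s < iv$end_s[j]
    region[hit] <- iv$label[j]
  }
  cycles$region <- region
  cycles
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf("<gait_cycles> %d cycles (%d typical, %d atypical; %d discarded as pauses)\n",
              nrow(x), sum(x$is_typical), sum(!x$is_typical),
              attr(x, "n_discarded")))
  if (nrow(x)) {
    tab <- sort(table(x$class_label), decreasing = TRUE)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
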