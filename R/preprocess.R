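# Debouncing of raw switch channels and encoding into the 4-level
# gait-phase signal.

# Merge adjacent equal-valued runs of an rle-style representation.
merge_adjacent_runs <- function(len, val) {
  k <- length(val)
  if (k <= 1L) return(list(len = len, val = val))
  grp <- cumsum(c(TRUE, val[-1L] != val[-k]))
  list(len = as.vector(rowsum(len, grp)), val = val[!duplicated(grp)])
}

# Iterated run-merge filter on an arbitrary vector: repeatedly replace the
# earliest shortest interior run of fewer than `min_len` samples with the
# value of the preceding run, until no such run remains.  Runs touching
# either end of the signal are never altered.
debounce_runs <- function(x, min_len) {
  r <- rle(x)
  len <- as.numeric(r$lengths)
  val <- r$values
  repeat {
    k <- length(len)
    if (k <= 2L) break
    interior <- 2:(k - 1L)
    short <- interior[len[interior] < min_len - 1e-9]
    if (!length(short)) break
    i <- short[which.min(len[short])]   # earliest among equal lengths
    val[i] <- val[i - 1L]
    m <- merge_adjacent_runs(len, val)
    len <- m$len
    val <- m$val
  }
  inverse.rle(structure(list(lengths = len, values = val), class = "rle"))
}

#' Anti-bounce filtering of switch channels
#'
#' Mechanical switch bounce produces spurious sub-millisecond to
#' few-millisecond toggles around contact events.  This zero-lag offline
#' filter removes every maximal constant run strictly shorter than
#' `min_run_s` from each channel by merging it into the preceding run,
#' iterating (earliest shortest run first) until a fixpoint is reached.
#' Runs touching the recording boundary are kept, since their true extent is
#' unobserved.  The operator is idempotent and, because it looks at future
#' samples as well as past ones, introduces no systematic lag: no level
#' transition moves by more than `min_run_s`.
#'
#' @param rec A [switch_recording()].
#' @param min_run_s Minimum run duration to keep, in seconds.  The default
#'   20 ms is far below physiological phase durations (~100-500 ms) and
#'   above typical switch-bounce artifacts.
#' @return The filtered [switch_recording()].
#' @export
debounce <- function(rec, min_run_s = 0.02) {
  stopifnot(inherits(rec, "switch_recording"))
  if (min_run_s < 0) stop("`min_run_s` must be non-negative")
  if (min_run_s >= recording_duration(rec))
    stop("`min_run_s` must be shorter than the recording")
  min_len <- min_run_s * rec$sampling_rate
  rec$heel <- debounce_runs(rec$heel, min_len)
  rec$met1 <- debounce_runs(rec$met1, min_len)
  rec$met5 <- debounce_runs(rec$met5, min_len)
  rec
}

# (heel, met1, met5) -> phase letter for the 8 switch states, indexed by
# heel*4 + met1*2 + met5 + 1.
PHASE_TABLE <- c("S", "P", "P", "P", "H", "F", "F", "F")

#' Encode switch channels into the 4-level gait-phase signal
#'
#' Per-sample mapping of the three switch states to the four foot-floor
#' contact phases:
#' * `H` (heel contact): only the heel switch is closed;
#' * `F` (flat-foot contact): the heel switch and at least one metatarsal
#'   switch are closed;
#' * `P` (push-off): at least one metatarsal switch is closed, heel open;
#' * `S` (swing): no switch is closed.
#'
#' The mapping is total over all eight switch combinations.  Because bounce
#' at a phase boundary can still create spurious one-or-two-sample phases
#' after encoding (when toggles on different channels interleave), an
#' optional second run-length pass removes phase runs shorter than
#' `min_phase_s` (on by default; set to 0 to disable).
#'
#' @param rec A [switch_recording()], normally already [debounce()]d.
#' @param min_phase_s Minimum phase-run duration in seconds for the second
#'   debounce pass over the encoded signal; 0 disables the pass.
#' @return An object of class `phase_signal`: a list with `labels`
#'   (character vector over `{"H","F","P","S"}`) and `sampling_rate`.
#' @export
encode_phases <- function(rec, min_phase_s = 0.02) {
  stopifnot(inherits(rec, "switch_recording"))
  labels <- PHASE_TABLE[rec$heel * 4L + rec$met1 * 2L + rec$met5 + 1L]
  if (min_phase_s > 0)
    labels <- debounce_runs(labels, min_phase_s * rec$sampling_rate)
  structure(list(labels = labels, sampling_rate = rec$sampling_rate),
            class = "phase_signal")
}

#' @export
print.phase_signal <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("H", "F", "P", "S")))
  cat(sprintf("<phase_signal> %d samples @ %g Hz | %s\n",
              length(x$labels), x$sampling_rate,
              paste(sprintf("%s %.1f%%", names(tab), 100 * tab / length(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
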