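# End-to-end orchestration: per-subject analysis, cohort aggregation and
# the cohort report (summary tables plus the statistical battery).

#' Analysis configuration
#'
#' Collects every tunable of the analysis chain in one object so that a run
#' is reproducible from its configuration alone.
#'
#' @param debounce_s Anti-bounce threshold in seconds (channel pass and
#'   phase pass).
#' @param max_cycle_s Segments longer than this are treated as pauses.
#' @param cadence_mode `"all"` or `"straight"` (see [summarize_side()]).
#' @param double_support_mode `"total"` or `"initial"` (see
#'   [double_support_pct()]).
#' @param g_pooling `"per_side"` (each subject contributes one value per
#'   side to the effect size) or `"subject_mean"` (sides averaged first).
#' @param ci_type Bootstrap interval type for correlations.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the stochastic stages (normality nulls, bootstrap).
#' @return A list of class `run_config`.
#' @export
run_config <- function(debounce_s = 0.02, max_cycle_s = 3,
                       cadence_mode = "all", double_support_mode = "total",
                       g_pooling = "per_side", ci_type = "bca",
                       n_boot = 1000, seed = NULL) {
  structure(list(debounce_s = debounce_s, max_cycle_s = max_cycle_s,
                 cadence_mode = cadence_mode,
                 double_support_mode = double_support_mode,
                 g_pooling = match.arg(g_pooling, c("per_side", "subject_mean")),
                 ci_type = match.arg(ci_type, c("bca", "percentile")),
                 n_boot = n_boot, seed = seed),
            class = "run_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Analyse one subject's bilateral recording
#'
#' Runs the full per-subject chain: debounce each side, encode the gait
#' phases, segment and classify the cycles, attribute them to straight/turn
#' regions, summarise each side, and compute walking speed, bilateral
#' double support and the speed-normalised atypical percentage.  The run is
#' deterministic given its inputs and configuration.
#'
#' @param left,right [switch_recording()]s of the two sides (either may be
#'   `NULL` for a single-side analysis; bilateral metrics are then `NA`).
#' @param annotations An [annotation_track()].
#' @param config A [run_config()].
#' @return A list of class `subject_result`: `sides` (per-side list with
#'   `summary`, `cycles`, `double_support_pct`, `atyp`), `speed` (m/s or
#'   `NA` if no timed passages), and `config`.
#' @export
analyze_subject <- function(left, right, annotations, config = run_config()) {
  if (is.null(left) && is.null(right)) stop("no recording given")
  recs <- list(left = left, right = right)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 1L)
    warning("single-side analysis: bilateral metrics will be NA")

  sigs <- lapply(recs, function(rec) {
    encode_phases(debounce(rec, config$debounce_s),
                  min_phase_s = config$debounce_s)
  })
  cycles <- lapply(sigs, function(sig)
    tag_regions(segment_cycles(sig, config$max_cycle_s), annotations))

  speed <- tryCatch(walking_speed(annotations), error = function(e) NA_real_)

  sides <- list()
  for (side in names(recs)) {
    other <- setdiff(names(recs), side)
    ds <- if (length(other)) {
      double_support_pct(sigs[[side]], sigs[[other]], cycles[[side]],
                         mode = config$double_support_mode)
    } else NA_real_
    summ <- summarize_side(cycles[[side]], recording_duration(recs[[side]]),
                           track = annotations,
                           cadence_mode = config$cadence_mode)
    atyp <- if (!is.na(speed) && !summ$empty)
      atyp_normalized(summ$pct_atypical, speed) else NA_real_
    sides[[side]] <- list(summary = summ, cycles = cycles[[side]],
                          double_support_pct = ds, atyp = atyp)
  }
  structure(list(sides = sides, speed = speed, config = config),
            class = "subject_result")
}

#' Per-cycle table of a subject result
#'
#' @param result A `subject_result`.
#' @return Data frame with one row per segmented cycle: side, start, end,
#'   class label, typicality, region.
#' @export
cycle_table <- function(result) {
  stopifnot(inherits(result, "subject_result"))
  do.call(rbind, lapply(names(result$sides), function(side) {
    cyc <- result$sides[[side]]$cycles
    if (!nrow(cyc)) return(NULL)
    data.frame(side = side,
               cyc[, c("start_s", "end_s", "duration_s", "class_label",
                       "is_typical", "region")],
               stringsAsFactors = FALSE)
  }))
}

#' Analyse a whole cohort
#'
#' Applies [analyze_subject()] to every subject and assembles the
#' subject-side results table that the cohort statistics operate on.
#'
#' @param cohort A `synth_cohort` from [simulate_cohort()], or a named list
#'   of subjects, each a list with `left`, `right`, `annotations`.
#' @param meta Metadata data frame (`subject_id`, `group`, `affected_side`,
#'   `updrs3`); taken from the cohort object when present.
#' @param config A [run_config()].
#' @return A data frame of class `cohort_result`, one row per subject-side:
#'   identity, role, `n_cycles`, `pct_typical`, `pct_atypical`, phase
#'   percentages `H`/`F`/`P`/`S`, `straight_atypical_pct`,
#'   `turn_atypical_pct`, `cadence`, `double_support_pct`, `speed`, `atyp`,
#'   `updrs3`.
#' @export
analyze_cohort <- function(cohort, meta = NULL, config = run_config()) {
  subjects <- if (inherits(cohort, "synth_cohort")) cohort$subjects else cohort
  if (is.null(meta) && inherits(cohort, "synth_cohort")) meta <- cohort$meta
  if (is.null(meta)) stop("cohort metadata required")
  rows <- list()
  for (id in names(subjects)) {
    sub <- subjects[[id]]
    m <- meta[meta$subject_id == id, , drop = FALSE]
    if (!nrow(m)) stop("no metadata for subject ", id)
    roles <- side_roles(m$group, m$affected_side)
    res <- analyze_subject(sub$left, sub$right, sub$annotations, config)
    for (side in names(res$sides)) {
      s <- res$sides[[side]]$summary
      rg <- res$sides[[side]]$summary$region_atypical_pct
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = m$group, side = side, role = roles[[side]],
        n_cycles = s$n_cycles, pct_typical = s$pct_typical,
        pct_atypical = s$pct_atypical,
        H = s$phase_pct[["H"]], F = s$phase_pct[["F"]],
        P = s$phase_pct[["P"]], S = s$phase_pct[["S"]],
        straight_atypical_pct = if ("straight" %in% names(rg)) rg[["straight"]] else 0,
        turn_atypical_pct = if ("turn" %in% names(rg)) rg[["turn"]] else 0,
        cadence = s$cadence,
        double_support_pct = res$sides[[side]]$double_support_pct,
        speed = res$speed, atyp = res$sides[[side]]$atyp,
        updrs3 = if ("updrs3" %in% names(m)) m$updrs3 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_result", "data.frame")
  out
}

# role -> printed column order
ROLE_ORDER <- c("more_affected", "less_affected", "dominant", "non_dominant")

#' Cohort summary tables and statistical battery
#'
#' Builds the two cohort tables (spatio-temporal and per-region
#' atypical-cycle statistics: mean and SD per group-side cell) and runs the
#' test battery: normality-screened two-group tests for the subject-level
#' parameters (speed, cadence, double support, side-averaged), two-way
#' Group x Side ANOVA with Tukey post-hoc and Hedges' g for the per-side
#' parameters, the control-referenced Atyp threshold and subgroup, and
#' bootstrap correlations between Atyp (more-affected side) and the motor
#' score for the whole patient group and for the above-threshold subgroup.
#'
#' @param cohort_df A `cohort_result` from [analyze_cohort()].
#' @param config A [run_config()]; its `seed` drives the normality nulls and
#'   the bootstrap.
#' @return A list of class `cohort_report`: `table1`, `table2`, `tests`,
#'   `anova` (named list of `gait_anova` objects), `subgroup`
#'   (threshold/mask), `correlations` (whole-group and subgroup
#'   `correlation_result`s, `NULL` when no motor scores are available).
#' @export
cohort_report <- function(cohort_df, config = run_config()) {
  stopifnot(inherits(cohort_df, "data.frame"))
  if (!nrow(cohort_df)) stop("empty cohort")
  if (!is.null(config$seed)) set.seed(config$seed)
  df <- cohort_df

  cell_stats <- function(values, groups) {
    out <- numeric(0)
    for (role in ROLE_ORDER) {
      v <- values[groups == role]
      out <- c(out, mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
    }
    names(out) <- paste(rep(ROLE_ORDER, each = 2), c("mean", "sd"), sep = "_")
    out
  }

  # subject-level (side-averaged) parameters: speed, cadence, double support
  subj <- aggregate(df[, c("cadence", "double_support_pct", "speed")],
                    by = list(subject_id = df$subject_id, group = df$group),
                    FUN = function(x) mean(x, na.rm = TRUE))
  two_groups_present <- length(unique(df$group)) == 2
  group_test <- function(param) {
    if (!two_groups_present) return(NA_real_)
    x <- subj[[param]][subj$group == "PD"]
    y <- subj[[param]][subj$group == "control"]
    if (sum(!is.na(x)) < 4 || sum(!is.na(y)) < 4) return(NA_real_)
    compare_two_groups(x[!is.na(x)], y[!is.na(y)])$p_value
  }

  t1_rows <- list()
  tests <- list()
  add_test <- function(param, method, statistic, p, g = NA_real_) {
    tests[[length(tests) + 1L]] <<- data.frame(
      parameter = param, method = method, statistic = statistic,
      p_value = p, hedges_g = g, stringsAsFactors = FALSE)
  }

  for (param in c("speed", "cadence", "double_support_pct")) {
    p <- group_test(param)
    cells <- rep(NA_real_, 8)
    names(cells) <- paste(rep(ROLE_ORDER, each = 2), c("mean", "sd"), sep = "_")
    for (grp in unique(subj$group)) {
      v <- subj[[param]][subj$group == grp]
      slot <- if (grp == "PD") "more_affected" else "dominant"
      cells[paste0(slot, "_mean")] <- mean(v, na.rm = TRUE)
      cells[paste0(slot, "_sd")] <- sd(v, na.rm = TRUE)
    }
    t1_rows[[param]] <- c(cells, p_group = p, p_side = NA_real_)
    add_test(param, "two-group (side-averaged)", NA_real_, p)
  }

  # per-side parameters: 2x2 ANOVA + Hedges' g on the Group contrast
  anovas <- list()
  per_side_params <- c(n_cycles = "n_cycles", pct_typical = "pct_typical",
                       H = "H", F = "F", P = "P", S = "S",
                       pct_atypical = "pct_atypical")
  g_for_group <- function(values) {
    if (!two_groups_present) return(NA_real_)
    if (config$g_pooling == "subject_mean") {
      agg <- aggregate(values, by = list(df$subject_id, df$group),
                       FUN = mean, na.rm = TRUE)
      x <- agg$x[agg$Group.2 == "PD"]; y <- agg$x[agg$Group.2 == "control"]
    } else {
      x <- values[df$group == "PD"]; y <- values[df$group == "control"]
    }
    tryCatch(hedges_g(x, y)$g, error = function(e) NA_real_)
  }
  for (param in names(per_side_params)) {
    v <- df[[per_side_params[[param]]]]
    ok <- !is.na(v)
    res <- if (two_groups_present && length(unique(df$role[ok])) >= 2) {
      side2 <- ifelse(df$role %in% c("more_affected", "dominant"),
                      "primary", "secondary")
      tryCatch(gait_anova(v[ok], df$group[ok], side2[ok]),
               error = function(e) NULL)
    } else NULL
    anovas[[param]] <- res
    p_group <- if (!is.null(res)) res$table$p[res$table$term == "group"] else NA_real_
    p_side <- if (!is.null(res)) res$table$p[res$table$term == "side"] else NA_real_
    g <- g_for_group(v)
    t1_rows[[param]] <- c(cell_stats(v, df$role), p_group = p_group, p_side = p_side)
    add_test(param, "two-way ANOVA (Group)",
             if (!is.null(res)) res$table$F[res$table$term == "group"] else NA_real_,
             p_group, g)
  }
  table1 <- data.frame(parameter = names(t1_rows),
                       do.call(rbind, t1_rows), row.names = NULL)

  t2_rows <- list()
  for (param in c(straight = "straight_atypical_pct", turn = "turn_atypical_pct")) {
    v <- df[[param]]
    ok <- !is.na(v)
    res <- if (two_groups_present && length(unique(df$role[ok])) >= 2) {
      side2 <- ifelse(df$role %in% c("more_affected", "dominant"),
                      "primary", "secondary")
      tryCatch(gait_anova(v[ok], df$group[ok], side2[ok]),
               error = function(e) NULL)
    } else NULL
    nm <- if (param == "straight_atypical_pct") "straight_walking" else "u_turning"
    anovas[[nm]] <- res
    p_group <- if (!is.null(res)) res$table$p[res$table$term == "group"] else NA_real_
    p_side <- if (!is.null(res)) res$table$p[res$table$term == "side"] else NA_real_
    t2_rows[[nm]] <- c(cell_stats(v, df$role), p_group = p_group, p_side = p_side)
    add_test(nm, "two-way ANOVA (Group)",
             if (!is.null(res)) res$table$F[res$table$term == "group"] else NA_real_,
             p_group, g_for_group(v))
  }
  table2 <- data.frame(parameter = names(t2_rows),
                       do.call(rbind, t2_rows), row.names = NULL)

  # Atyp subgroup and motor-score correlations (more-affected side)
  subgroup <- NULL
  correlations <- NULL
  pd_more <- df[df$role == "more_affected" & !is.na(df$atyp), , drop = FALSE]
  ctl <- df[df$group == "control" & !is.na(df$atyp), , drop = FALSE]
  if (nrow(ctl) && nrow(pd_more)) {
    ctl_subj <- aggregate(atyp ~ subject_id, data = ctl, FUN = mean)
    subgroup <- select_subgroup(pd_more$atyp, ctl_subj$atyp)
    subgroup$subject_id <- pd_more$subject_id[subgroup$selected]
    has_updrs <- !is.na(pd_more$updrs3)
    if (sum(has_updrs) >= 3 && sd(pd_more$atyp[has_updrs]) > 0) {
      whole <- pearson_bootstrap(pd_more$atyp[has_updrs],
                                 pd_more$updrs3[has_updrs],
                                 n_boot = config$n_boot,
                                 ci_type = config$ci_type)
      sel <- subgroup$selected & has_updrs
      sub_r <- if (sum(sel) >= 3 && sd(pd_more$atyp[sel]) > 0)
        pearson_bootstrap(pd_more$atyp[sel], pd_more$updrs3[sel],
                          n_boot = config$n_boot, ci_type = config$ci_type)
      else NULL
      correlations <- list(whole_group = whole, subgroup = sub_r)
      add_test("atyp_vs_updrs3 (whole PD)", "Pearson + bootstrap CI",
               whole$r, whole$p_value)
      if (!is.null(sub_r))
        add_test("atyp_vs_updrs3 (subgroup)", "Pearson + bootstrap CI",
                 sub_r$r, sub_r$p_value)
    }
  }

  structure(list(table1 = table1, table2 = table2,
                 tests = do.call(rbind, tests), anova = anovas,
                 subgroup = subgroup, correlations = correlations,
                 config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort gait parameters (mean per group-side cell):\n")
  print(fmt_table(x$table1), row.names = FALSE)
  cat("\nAtypical cycles by walking-path region:\n")
  print(fmt_table(x$table2), row.names = FALSE)
  if (!is.null(x$subgroup))
    cat(sprintf("\nAtyp threshold (control mean + SD): %.1f; %d patients above\n",
                x$subgroup$threshold, x$subgroup$n_selected))
  if (!is.null(x$correlations)) {
    cat("\nAtyp vs motor score:\n  whole PD group:  ")
    print(x$correlations$whole_group)
    if (!is.null(x$correlations$subgroup)) {
      cat("  above-threshold: ")
      print(x$correlations$subgroup)
    }
  }
  invisible(x)
}
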