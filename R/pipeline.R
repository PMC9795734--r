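# Orchestration: simulate -> QC -> metrics -> statistics as reproducible
# steps. Every step writes tidy CSV plus a JSON run manifest (config
# snapshot, input checksums, seed, package version, per-stage counts) so
# each output table is traceable.

.manifest <- function(stage, config, seed = NULL, inputs = character(0),
                      counts = list()) {
  list(
    stage = stage,
    package_version = as.character(utils::packageVersion("vabtrack")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = if (inherits(config, "session_config")) unclass(config) else config,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    counts = counts
  )
}

.write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a batch of sessions to disk
#'
#' Writes `n` synthetic sessions as pose-track CSVs plus line-delimited JSON
#' ground-truth event logs and a run manifest. Deterministic under
#' `(params, seed)`: session i uses seed `seed + i - 1`.
#'
#' @param n number of sessions.
#' @param out_dir output directory (created if needed).
#' @param params a [sim_params] template; its `seed` field is overridden
#'   per session.
#' @param seed base seed.
#' @param prefix file-name prefix; default `"session"`.
#' @return data.frame listing per-session `track_path`, `truth_path`, `seed`.
#' @export
run_simulate <- function(n, out_dir, params = sim_params(), seed = 1L,
                         prefix = "session") {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- as.integer(seed + i - 1L)
    sim <- simulate_session(p)
    tp <- file.path(out_dir, sprintf("%s_%03d_tracks.csv", prefix, i))
    gp <- file.path(out_dir, sprintf("%s_%03d_truth.jsonl", prefix, i))
    write_tracks(sim$tracks, tp)
    write_event_log(sim$truth$events, gp)
    data.frame(track_path = tp, truth_path = gp, seed = p$seed)
  })
  index <- do.call(rbind, rows)
  man <- .manifest("simulate", unclass(params), seed = seed,
                   inputs = index$track_path,
                   counts = list(n_sessions = n,
                                 n_frames_per_session =
                                   round(params$fps * params$session_duration_s)))
  .write_manifest(man, file.path(out_dir, paste0(prefix, "_manifest.json")))
  index
}

#' Analyze track files into behavior summaries
#'
#' For every track file: read (splitting arenas per the config), QC (flag
#' sub-threshold frames and interpolate), calibrate, and summarize. Emits
#' one BehaviorSummary row per session per arena and a combined event table.
#'
#' @param track_paths character vector of pose-track CSV paths (non-empty).
#' @param config a [session_config].
#' @param out_dir optional directory; when given, `behavior_summary.csv`,
#'   `events.csv` and `analyze_manifest.json` are written there.
#' @return list with `summary` (data.frame; columns `source`, `arena_id`,
#'   `fish_id`, QC counts, and the [summarize_behavior] columns) and
#'   `events` (data.frame with `fish_id` prepended).
#' @export
run_analyze <- function(track_paths, config = session_config(),
                        out_dir = NULL) {
  if (length(track_paths) == 0L) {
    stop("run_analyze: empty session list; nothing to analyze")
  }
  missing <- track_paths[!file.exists(track_paths)]
  if (length(missing)) {
    stop("run_analyze: missing track file(s): ", paste(missing, collapse = ", "))
  }
  sum_rows <- list(); ev_rows <- list()
  for (path in track_paths) {
    arenas <- tryCatch(read_tracks(path, config), error = function(e) {
      stop("run_analyze: failed to read '", path, "': ", conditionMessage(e))
    })
    for (ts in arenas) {
      ts$pixels_per_cm <- derive_calibration(config, ts)
      clean <- qc_tracks(ts, config)
      qc <- attr(clean, "qc_report")
      fish_id <- paste0(tools::file_path_sans_ext(basename(path)), ":",
                        ts$arena_id)
      s <- summarize_behavior(clean, config$radius_cm)
      s <- cbind(data.frame(source = path, arena_id = ts$arena_id,
                            fish_id = fish_id,
                            n_frames = n_frames(clean),
                            n_frames_repaired = qc$n_flagged,
                            n_repair_runs = length(qc$run_lengths)), s)
      sum_rows[[length(sum_rows) + 1L]] <- s
      ev <- detect_approaches(clean, config$radius_cm)
      if (nrow(ev)) {
        ev_rows[[length(ev_rows) + 1L]] <- cbind(data.frame(fish_id = fish_id),
                                                 ev)
      }
    }
  }
  summary <- do.call(rbind, sum_rows)
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(fish_id = character(0), entry_frame = integer(0),
               exit_frame = integer(0), side = character(0),
               dwell_s = numeric(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    man <- .manifest("analyze", config, inputs = track_paths,
                     counts = list(n_files = length(track_paths),
                                   n_summary_rows = nrow(summary),
                                   n_events = nrow(events)))
    .write_manifest(man, file.path(out_dir, "analyze_manifest.json"))
  }
  list(summary = summary, events = events)
}

#' Laterality statistics over a cohort
#'
#' Builds per-fish laterality records and a long-format statistics table:
#' per-population preference counts, ICC repeatability when a repeats matrix
#' is supplied, Kendall correlations between requested covariate/measure
#' column pairs, and paired Wilcoxon tests with Holm correction when a
#' fasting design (before/after conditions) is supplied.
#'
#' @param summaries per-fish behavior summary data.frame (`fish_id` required;
#'   `population` and `condition` columns used when present).
#' @param sensory optional covariate table keyed by `fish_id` (see
#'   [laterality_records]).
#' @param repeats optional named list of subjects-by-repeats matrices, one
#'   per population, for [icc_repeatability].
#' @param correlations optional data.frame with columns `x` and `y` naming
#'   record columns to correlate by [kendall_correlation].
#' @param fasting logical; when `TRUE`, `summaries$condition` must contain
#'   `"before"` and `"after"` rows and the Wilcoxon/Holm family of NOA and
#'   DIR changes is computed.
#' @param out_dir optional output directory for the CSVs and manifest.
#' @return list with `records` (LateralityRecord rows) and `stats`
#'   (long-format: `analysis`, `group`, `statistic`, `value`, `p`, `p_holm`).
#' @export
run_stats <- function(summaries, sensory = NULL, repeats = NULL,
                      correlations = NULL, fasting = FALSE, out_dir = NULL) {
  records <- laterality_records(summaries, sensory)
  long <- list()
  add <- function(analysis, group, statistic, value, p = NA_real_,
                  p_holm = NA_real_) {
    long[[length(long) + 1L]] <<- data.frame(
      analysis = analysis, group = group, statistic = statistic,
      value = value, p = p, p_holm = p_holm)
  }

  pops <- if ("population" %in% names(records)) unique(records$population)
          else "all"
  for (pop in pops) {
    rec <- if ("population" %in% names(records))
      records[records$population == pop, ] else records
    for (pref in c("left", "balanced", "right", "undefined")) {
      add("preference_count", pop, pref, sum(rec$preference == pref))
    }
    add("lr_noa_ratio_mean", pop, "mean",
        mean(rec$lr_noa_ratio, na.rm = TRUE))
  }

  for (pop in names(repeats %||% list())) {
    icc <- icc_repeatability(repeats[[pop]])
    add("icc_repeatability", pop, "kappa_consistency", icc$kappa,
        p = icc$p_value)
    add("icc_repeatability", pop, "kappa_agreement", icc$kappa_agreement,
        p = icc$p_value)
    add("icc_repeatability", pop, "F", icc$f, p = icc$p_value)
  }

  if (!is.null(correlations)) {
    for (i in seq_len(nrow(correlations))) {
      xc <- correlations$x[i]; yc <- correlations$y[i]
      miss <- setdiff(c(xc, yc), names(records))
      if (length(miss)) {
        stop("run_stats: correlation columns missing from records: ",
             paste(miss, collapse = ", "),
             " (fish lacking covariates: ",
             paste(records$fish_id[!stats::complete.cases(
               records[intersect(c(xc, yc), names(records))])],
               collapse = ", "), ")")
      }
      ok <- stats::complete.cases(records[c(xc, yc)])
      kt <- kendall_correlation(records[[xc]][ok], records[[yc]][ok])
      add("kendall", paste0(xc, "~", yc), "tau", kt$tau, p = kt$p_value)
    }
  }

  if (isTRUE(fasting)) {
    if (!("condition" %in% names(records)) ||
        !all(c("before", "after") %in% records$condition)) {
      stop("run_stats: fasting analysis needs both 'before' and 'after' ",
           "conditions in the summaries")
    }
    bef <- records[records$condition == "before", ]
    aft <- records[records$condition == "after", ]
    fam <- list(
      noa_total = list(before = bef$noa_total[order(bef$fish_id)],
                       after = aft$noa_total[order(aft$fish_id)]),
      dir_total_s = list(before = bef$dir_total_s[order(bef$fish_id)],
                         after = aft$dir_total_s[order(aft$fish_id)])
    )
    wt <- paired_wilcoxon_holm(fam)
    for (i in seq_len(nrow(wt))) {
      add("wilcoxon_fasting", wt$test[i], "V", wt$v_statistic[i],
          p = wt$p_value[i], p_holm = wt$p_holm[i])
    }
  }

  stats_tab <- do.call(rbind, long)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "laterality_records.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(out_dir, "laterality_stats.csv"),
                     row.names = FALSE)
    man <- .manifest("stats", list(fasting = fasting),
                     counts = list(n_records = nrow(records),
                                   n_stats_rows = nrow(stats_tab)))
    .write_manifest(man, file.path(out_dir, "stats_manifest.json"))
  }
  list(records = records, stats = stats_tab)
}
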