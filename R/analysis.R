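# Config-driven analysis runner: monitor files -> validation -> layout ->
# viability -> activity -> sleep -> circadian, with every table exported as
# CSV (comma-separated, UTF-8, ISO-8601 dates) and a manifest of outputs.
# Re-running the same config on the same inputs reproduces the CSVs
# byte-identically; the run log echoes settings but no wall-clock time.

#' Read and validate an analysis configuration
#'
#' Loads a YAML configuration describing monitor files, the experiment
#' layout (conditions, channels, LD/DD date ranges, light onset, interval,
#' dead-fly threshold) and the analysis settings (regimes to analyse, sleep
#' window, bin widths, periodogram settings, plot dimensions). Unknown or
#' inconsistent settings are reported before any analysis runs.
#'
#' @param path Path to a YAML config file (see the package README for the
#'   schema and a worked example).
#' @return A validated config list of class `dam_config`.
#' @export
read_analysis_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(interval_minutes = 1, light_onset = "06:00",
                   day_length_hours = 12, dead_threshold = 50,
                   analyze = "both", sleep_window_minutes = 5,
                   profile_bin_minutes = 30, actogram_bin_minutes = 30,
                   plots = TRUE,
                   periodogram = list(min_h = 18, max_h = 30,
                                      resolution_h = 0.1, alpha = 0.05,
                                      correction = "sidak",
                                      strength_threshold = 1),
                   plot = list(width = 8, height = 5, ymax = NULL),
                   output_dir = "dam_output")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  problems <- character(0)
  if (is.null(cfg$monitors) || length(cfg$monitors) == 0L) {
    problems <- c(problems, "no monitors listed; add 'monitors: [{id, path}]'")
  }
  if (is.null(cfg$conditions) || length(cfg$conditions) == 0L) {
    problems <- c(problems,
                  "no conditions listed; add 'conditions: [{name, monitor, channels}]'")
  }
  if (!cfg$analyze %in% c("LD", "DD", "both")) {
    problems <- c(problems,
                  sprintf("analyze must be LD, DD or both (got '%s')", cfg$analyze))
  }
  has_ld <- !is.null(cfg$ld_start)
  has_dd <- !is.null(cfg$dd_start)
  if (!has_ld && !has_dd) {
    problems <- c(problems,
                  "neither LD nor DD date range given; set ld_start/ld_end and/or dd_start/dd_end")
  }
  if (cfg$analyze %in% c("LD", "both") && !has_ld && has_dd) {
    cfg$analyze <- "DD"
  }
  if (cfg$analyze %in% c("DD", "both") && !has_dd && has_ld) {
    cfg$analyze <- "LD"
  }
  if (length(problems) > 0L) {
    stop("settings conflict(s):\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  class(cfg) <- "dam_config"
  cfg
}

#' Build an experiment layout from a config
#'
#' @param config A `dam_config` from [read_analysis_config()], or an
#'   equivalent list.
#' @return An [experiment_layout()].
#' @export
config_layout <- function(config) {
  cal <- light_calendar(
    ld_start = config$ld_start, ld_end = config$ld_end,
    dd_start = config$dd_start, dd_end = config$dd_end,
    light_onset = config$light_onset,
    day_length_hours = config$day_length_hours)
  conds <- lapply(config$conditions, function(cn) {
    condition(cn$name, cn$monitor,
              channels = if (is.null(cn$channels)) 1:32
                         else as.integer(unlist(cn$channels)),
              color = if (is.null(cn$color)) "#333333" else cn$color)
  })
  experiment_layout(conds, cal, config$interval_minutes,
                    config$dead_threshold)
}

write_table <- function(df, dir, name, manifest) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  c(manifest, name)
}

#' Run the full analysis described by a config
#'
#' Executes the whole pipeline — file reading and validation, regime
#' labelling, dead-fly exclusion, activity and sleep statistics, bout
#' statistics, periodograms and actograms — and writes every table as CSV
#' (plus plots unless disabled) into `out_dir`, together with `run_log.txt`
#' (settings echo and issue table) and `manifest.json` listing the outputs.
#'
#' @param config A `dam_config`, or a path to a YAML config file.
#' @param out_dir Output directory (created if missing); defaults to the
#'   config's `output_dir`.
#' @param base_dir Directory monitor paths are resolved against; defaults
#'   to the config file's directory when `config` is a path.
#' @return Invisibly, the manifest: list with `outputs` (relative file
#'   names), `n_fatal_issues`, `out_dir`.
#' @export
run_analysis <- function(config, out_dir = NULL, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- read_analysis_config(config)
  }
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log <- c("flydam analysis run", "settings:",
           paste0("  ", utils::capture.output(utils::str(
             config[setdiff(names(config), c("monitors", "conditions"))],
             give.attr = FALSE))))

  layout <- config_layout(config)
  monitors <- list()
  all_issues <- empty_issues()
  for (mspec in config$monitors) {
    p <- mspec$path
    if (!file.exists(p) && file.exists(file.path(base_dir, p))) {
      p <- file.path(base_dir, p)
    }
    mon <- read_monitor_file(p, config$interval_minutes,
                             monitor_id = mspec$id)
    monitors[[mspec$id]] <- mon
    all_issues <- rbind(all_issues, mon$issues)
  }
  log <- c(log, sprintf("monitors loaded: %d", length(monitors)),
           sprintf("validation issues (non-fatal): %d", nrow(all_issues)))
  if (nrow(all_issues) > 0L) {
    log <- c(log, utils::capture.output(print(all_issues)))
  }

  series <- extract_fly_series(monitors, layout)
  via <- viability_report(series, layout)
  manifest <- write_table(via$flies, out_dir, "dead_flies.csv", manifest)
  manifest <- write_table(via$conditions, out_dir, "condition_counts.csv",
                          manifest)
  alive <- exclude_dead(series, via)
  log <- c(log, sprintf("flies assigned: %d, dead: %d, analyzed: %d",
                        length(series), length(series) - length(alive),
                        length(alive)))
  if (length(alive) == 0L) {
    stop("every fly fell below the dead-fly threshold; nothing to analyze",
         call. = FALSE)
  }
  cal <- layout$calendar
  fd <- fly_day_table(alive, cal)
  manifest <- write_table(fd, out_dir,
                          "daily_locomotor_activity_by_fly.csv", manifest)

  do_ld <- config$analyze %in% c("LD", "both") && !is.null(cal$ld_dates)
  do_dd <- config$analyze %in% c("DD", "both") && !is.null(cal$dd_dates)
  if (do_ld) {
    ld_sum <- do.call(rbind, lapply(c("all", "day", "night"), function(ph) {
      condition_daily_activity(fd, "LD", ph)$summary
    }))
    manifest <- write_table(ld_sum, out_dir, "condition_summary_LD.csv",
                            manifest)
  } else {
    log <- c(log, "LD summaries skipped (no LD days analyzed)")
  }
  if (do_dd) {
    manifest <- write_table(condition_daily_activity(fd, "DD")$summary,
                            out_dir, "condition_summary_DD.csv", manifest)
  } else {
    log <- c(log, "DD summaries skipped (no DD days analyzed)")
  }
  manifest <- write_table(activity_by_day(fd), out_dir,
                          "activity_by_day.csv", manifest)

  prof <- activity_profile(alive, cal, config$profile_bin_minutes,
                           "full_experiment")
  prof$mode <- "full_experiment"
  if (do_ld) {
    ldp <- activity_profile(alive, cal, config$profile_bin_minutes,
                            "ld_average")
    ldp$mode <- "ld_average"
    ldp$bin_start <- as.character(ldp$bin_start)
    prof$bin_start <- as.character(prof$bin_start)
    prof <- rbind(prof, ldp)
  } else {
    prof$bin_start <- as.character(prof$bin_start)
  }
  manifest <- write_table(prof, out_dir, "activity_profile.csv", manifest)

  states <- lapply(alive, detect_sleep,
                   window_minutes = config$sleep_window_minutes)
  sleep_by_fly <- do.call(rbind, c(lapply(states, function(st) {
    s <- sleep_summary(st, cal)
    cbind(fly_id = st$fly_id, condition = st$condition, s)
  }), list(make.row.names = FALSE)))
  manifest <- write_table(sleep_by_fly, out_dir,
                          "sleep_day_night_by_fly.csv", manifest)

  sprof <- sleep_profile(states, cal, config$profile_bin_minutes,
                         "full_experiment")
  sprof$bin_start <- as.character(sprof$bin_start)
  manifest <- write_table(sprof, out_dir, "sleep_profile.csv", manifest)

  bouts <- do.call(rbind, c(unlist(recursive = FALSE, lapply(
    seq_along(alive), function(i) {
      ab <- activity_bouts(alive[[i]], cal)
      sb <- sleep_bouts(states[[i]], cal)
      list(cbind(fly_id = alive[[i]]$fly_id,
                 condition = alive[[i]]$condition, type = "activity", ab),
           cbind(fly_id = alive[[i]]$fly_id,
                 condition = alive[[i]]$condition, type = "sleep", sb))
    })), list(make.row.names = FALSE)))
  manifest <- write_table(bouts, out_dir, "bout_stats_by_fly.csv", manifest)

  pgs <- NULL
  if (do_dd) {
    pg <- config$periodogram
    pgs <- lapply(alive, function(s) {
      chi_square_periodogram(
        s, period_range = c(pg$min_h, pg$max_h),
        resolution_h = pg$resolution_h, alpha = pg$alpha,
        correction = pg$correction,
        strength_threshold = pg$strength_threshold,
        calendar = cal, use_regime = "DD")
    })
    pg_long <- do.call(rbind, c(lapply(pgs, function(r) {
      cbind(fly_id = r$fly_id, condition = r$condition,
            r$table[, c("period_h", "Q", "S")])
    }), list(make.row.names = FALSE)))
    manifest <- write_table(pg_long, out_dir, "periodogram_by_fly.csv",
                            manifest)
    per_fly <- do.call(rbind, c(lapply(pgs, function(r) {
      data.frame(fly_id = r$fly_id, condition = r$condition,
                 peak_period = r$peak_period,
                 rhythm_strength = r$rhythm_strength,
                 rhythmic = r$rhythmic)
    }), list(make.row.names = FALSE)))
    manifest <- write_table(per_fly, out_dir,
                            "circadian_period_by_fly.csv", manifest)
    log <- c(log, sprintf("rhythmic flies: %d / %d",
                          sum(per_fly$rhythmic), nrow(per_fly)))
  } else {
    log <- c(log, "circadian analysis skipped (no DD days analyzed)")
  }

  acto_long <- NULL
  for (cn in unique(vapply(alive, function(s) s$condition, character(1)))) {
    sub <- alive[vapply(alive, function(s) s$condition == cn, logical(1))]
    act <- build_actogram(sub, cal, config$actogram_bin_minutes,
                          style = "double", stat = "mean")
    long <- data.frame(condition = cn,
                       day = rep(as.character(act$days), ncol(act$matrix)),
                       bin_h = rep(as.numeric(colnames(act$matrix)),
                                   each = nrow(act$matrix)),
                       value = as.numeric(act$matrix))
    acto_long <- rbind(acto_long, long)
  }
  manifest <- write_table(acto_long, out_dir, "actogram_mean.csv", manifest)

  if (isTRUE(config$plots)) {
    manifest <- c(manifest, write_plots(
      out_dir, config, fd = fd, prof = prof, sprof = sprof,
      pgs = pgs, acto = acto_long, do_ld = do_ld, do_dd = do_dd))
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  man <- list(outputs = c(manifest, "run_log.txt", "manifest.json"),
              n_fatal_issues = 0L, out_dir = out_dir)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
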