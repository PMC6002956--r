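# Experiment layout and time machinery: light-regime calendar, onset-anchored
# experimental days, condition -> channel mapping, and binning.
#
# Experimental days run light-onset -> next light-onset (not midnight to
# midnight), so each LD day contains one full day phase followed by one full
# night phase. The same onset-anchored boundary is kept in DD (subjective
# day), since the free-running phase is unknown.

#' Light-regime calendar
#'
#' Describes which calendar dates of an experiment were run under a
#' light:dark cycle (LD) and which under constant darkness (DD), plus the
#' clock time of lights-on and the photoperiod length.
#'
#' @param ld_start,ld_end Inclusive date range of LD days (anything coercible
#'   by `as.Date`), or both `NULL` for no LD phase.
#' @param dd_start,dd_end Inclusive date range of DD days, or both `NULL`.
#' @param light_onset Clock time of lights-on, `"HH:MM"` / `"HH:MM:SS"` or
#'   seconds since midnight. Anchors day/night phases and experimental-day
#'   boundaries.
#' @param day_length_hours Length of the light phase in hours (0-24,
#'   exclusive); the classic paradigm uses 12.
#' @return A `light_calendar` object.
#' @export
light_calendar <- function(ld_start = NULL, ld_end = NULL,
                           dd_start = NULL, dd_end = NULL,
                           light_onset = "06:00", day_length_hours = 12) {
  stopifnot(day_length_hours > 0, day_length_hours < 24)
  ld <- if (is.null(ld_start)) NULL else c(as.Date(ld_start), as.Date(ld_end))
  dd <- if (is.null(dd_start)) NULL else c(as.Date(dd_start), as.Date(dd_end))
  if (!is.null(ld)) stopifnot(ld[1L] <= ld[2L])
  if (!is.null(dd)) stopifnot(dd[1L] <= dd[2L])
  if (!is.null(ld) && !is.null(dd) && ld[1L] <= dd[2L] && dd[1L] <= ld[2L]) {
    stop(sprintf("LD dates (%s..%s) overlap DD dates (%s..%s); the regimes must not share days",
                 ld[1L], ld[2L], dd[1L], dd[2L]), call. = FALSE)
  }
  structure(list(ld_dates = ld, dd_dates = dd,
                 light_onset = parse_time_of_day(light_onset),
                 day_length_hours = day_length_hours),
            class = "light_calendar")
}

#' @export
print.light_calendar <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "none" else paste(r[1L], "..", r[2L])
  cat(sprintf("<light_calendar> LD %s | DD %s | onset %02d:%02d | day %g h\n",
              fmt(x$ld_dates), fmt(x$dd_dates),
              x$light_onset %/% 3600, (x$light_onset %% 3600) %/% 60,
              x$day_length_hours))
  invisible(x)
}

#' Experimental condition
#'
#' A named group of flies (genotype, treatment, ...) assigned to monitor
#' channels; each channel holds one fly and belongs to at most one condition.
#'
#' @param name Condition label used in outputs.
#' @param monitor Monitor id the channels belong to (a single string, or a
#'   vector parallel to `channels` for layouts spanning monitors).
#' @param channels Integer channel numbers, 1-32.
#' @param color Hex colour used for this condition in plots.
#' @return A `dam_condition` object.
#' @export
condition <- function(name, monitor, channels = 1:32, color = "#333333") {
  stopifnot(length(channels) >= 1L, all(channels %in% 1:32))
  if (length(monitor) == 1L) monitor <- rep(monitor, length(channels))
  stopifnot(length(monitor) == length(channels))
  structure(list(name = name, color = color,
                 channel_refs = data.frame(monitor_id = monitor,
                                           channel = as.integer(channels))),
            class = "dam_condition")
}

#' Experiment layout
#'
#' Bundles the condition -> channel assignments with the light calendar, the
#' acquisition interval, and the dead-fly threshold.
#'
#' @param conditions List of [condition()] objects; no channel may appear in
#'   two conditions.
#' @param calendar A [light_calendar()].
#' @param interval_minutes Acquisition interval of the monitors, minutes.
#' @param dead_threshold Counts/day below which a fly is considered dead on
#'   that day (see [flag_dead()]).
#' @return An `experiment_layout` object.
#' @export
experiment_layout <- function(conditions, calendar, interval_minutes = 1,
                              dead_threshold = 50) {
  stopifnot(inherits(calendar, "light_calendar"), interval_minutes > 0,
            dead_threshold >= 0, length(conditions) >= 1L)
  refs <- do.call(rbind, lapply(conditions, function(cn) cn$channel_refs))
  key <- paste(refs$monitor_id, refs$channel)
  if (anyDuplicated(key)) {
    stop("channel assigned to two conditions: ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  structure(list(conditions = conditions, calendar = calendar,
                 interval_minutes = interval_minutes,
                 dead_threshold = dead_threshold),
            class = "experiment_layout")
}

#' Label readings with regime, phase and experimental day
#'
#' Maps timestamps onto the experiment's structure: the experimental day is
#' the onset-anchored day that began at the most recent light onset; the
#' regime (`LD`, `DD`, `excluded`) follows from which date range that day
#' falls in; within LD the phase is `day` iff the time of day lies in
#' `[light_onset, light_onset + day_length_hours)`, and `night` otherwise.
#' In DD (and for excluded days) the phase is `none`.
#'
#' @param t POSIXct vector of reading timestamps.
#' @param calendar A [light_calendar()].
#' @return Data frame with one row per timestamp: `regime`, `phase`,
#'   `experimental_day` (Date).
#' @export
label_reading <- function(t, calendar) {
  stopifnot(inherits(calendar, "light_calendar"))
  sec <- as.numeric(t)
  eday <- as.Date(floor((sec - calendar$light_onset) / 86400),
                  origin = "1970-01-01")
  regime <- rep("excluded", length(t))
  ld <- calendar$ld_dates
  dd <- calendar$dd_dates
  if (!is.null(ld)) regime[eday >= ld[1L] & eday <= ld[2L]] <- "LD"
  if (!is.null(dd)) regime[eday >= dd[1L] & eday <= dd[2L]] <- "DD"
  since_onset <- (sec - calendar$light_onset) %% 86400
  phase <- rep("none", length(t))
  is_ld <- regime == "LD"
  phase[is_ld] <- ifelse(
    since_onset[is_ld] < calendar$day_length_hours * 3600, "day", "night")
  data.frame(regime = regime, phase = phase, experimental_day = eday)
}

#' Construct a count series from a plain vector
#'
#' Wraps a numeric vector of beam-crossing counts (or any event counts on a
#' regular grid) as the `count_series` object the analysis functions accept,
#' for data that does not come from a monitor file.
#'
#' @param count Numeric vector of non-negative counts, one per reading.
#' @param interval_minutes Spacing of readings, minutes.
#' @param start Timestamp of the first reading (POSIXct or parseable
#'   string; taken as UTC).
#' @param fly_id,condition Labels carried into downstream tables.
#' @return A `count_series`.
#' @export
count_series <- function(count, interval_minutes = 1,
                         start = "2017-01-01 06:00:00",
                         fly_id = "fly", condition = "cond") {
  stopifnot(length(count) >= 1L, all(count >= 0), interval_minutes > 0)
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- t0 + (seq_along(count) - 1L) * interval_minutes * 60
  new_count_series(fly_id, condition, NA_character_, NA_integer_,
                   ts, count, interval_minutes)
}

# all dates covered by the calendar, in order; c() would strip the Date
# class when the first range is NULL, hence the list-based combine
calendar_dates <- function(calendar) {
  out <- Filter(Negate(is.null),
                list(calendar$ld_dates, calendar$dd_dates))
  sort(do.call(c, out))
}

new_count_series <- function(fly_id, condition, monitor_id, channel,
                             timestamp, count, interval_minutes) {
  structure(list(fly_id = fly_id, condition = condition,
                 monitor_id = monitor_id, channel = channel,
                 timestamp = timestamp, count = as.numeric(count),
                 interval_minutes = interval_minutes),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series '%s'> %d readings @ %g min, total %g\n",
              x$fly_id, length(x$count), x$interval_minutes, sum(x$count)))
  invisible(x)
}

#' Extract per-fly count series from loaded monitors
#'
#' Pulls one beam-crossing count series per assigned channel, restricted to
#' the calendar's LD and DD dates. Fly ids are
#' `"<condition>_<monitor>_<channel>"`. Readings that were dropped during
#' validation (hardware-error rows) leave holes in the monitor grid; these
#' are filled with zero counts so every series lies on a complete grid.
#'
#' @param monitors Named list of `dam_monitor` objects, names = monitor ids.
#' @param layout An [experiment_layout()].
#' @return Named list of `count_series`, one per assigned fly.
#' @export
extract_fly_series <- function(monitors, layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  step <- layout$interval_minutes
  grids <- lapply(monitors, function(mon) {
    stopifnot(inherits(mon, "dam_monitor"))
    if (abs(mon$interval_minutes - step) > 1e-9) {
      stop(sprintf("settings conflict: monitor '%s' was read at %g min but the layout declares %g min",
                   mon$monitor_id, mon$interval_minutes, step), call. = FALSE)
    }
    ts <- mon$records$timestamp
    full <- seq(ts[1L], ts[length(ts)], by = step * 60)
    pos <- match(as.numeric(full), as.numeric(ts))
    lab <- label_reading(full, layout$calendar)
    keep <- lab$regime != "excluded"
    list(full = full[keep], pos = pos[keep])
  })
  out <- list()
  for (cn in layout$conditions) {
    refs <- cn$channel_refs
    for (i in seq_len(nrow(refs))) {
      mid <- refs$monitor_id[i]
      ch <- refs$channel[i]
      if (!mid %in% names(monitors)) {
        stop(sprintf("settings conflict: condition '%s' references monitor '%s' which is not loaded; load the file or fix the layout",
                     cn$name, mid), call. = FALSE)
      }
      g <- grids[[mid]]
      cnt <- monitors[[mid]]$counts[g$pos, ch]
      cnt[is.na(cnt)] <- 0
      fly_id <- sprintf("%s_%s_%02d", cn$name, mid, ch)
      out[[fly_id]] <- new_count_series(fly_id, cn$name, mid, ch,
                                        g$full, cnt, step)
    }
  }
  out
}

#' Bin a count series into coarser time windows
#'
#' Aggregates consecutive readings into non-overlapping bins aligned to the
#' light onset, so bin boundaries coincide with phase boundaries. Bins with
#' fewer than `bin_minutes / interval` readings (partial bins at either end)
#' are dropped.
#'
#' @param series A `count_series`.
#' @param bin_minutes Bin width in minutes; must be a multiple of the series'
#'   interval.
#' @param statistic `"sum"` (total counts per bin) or `"mean"` (average
#'   counts per reading).
#' @param light_onset Bin-grid anchor as seconds since midnight or a
#'   `light_calendar`; defaults to midnight.
#' @return A `count_series` whose `interval_minutes` is `bin_minutes` and
#'   whose timestamps are the bin start times.
#' @export
bin_series <- function(series, bin_minutes, statistic = c("sum", "mean"),
                       light_onset = 0) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(series, "count_series"), bin_minutes > 0)
  step <- series$interval_minutes
  if (abs(bin_minutes / step - round(bin_minutes / step)) > 1e-9) {
    stop(sprintf("bin of %g min is not a multiple of the %g-min acquisition interval",
                 bin_minutes, step), call. = FALSE)
  }
  per_bin <- as.integer(round(bin_minutes / step))
  if (per_bin == 1L) return(series)
  onset <- if (inherits(light_onset, "light_calendar")) {
    light_onset$light_onset
  } else as.numeric(light_onset)
  sec <- as.numeric(series$timestamp)
  bin <- floor((sec - onset) / (bin_minutes * 60))
  agg <- tapply(series$count, bin, if (statistic == "sum") sum else mean)
  n_in_bin <- tapply(series$count, bin, length)
  keep <- n_in_bin == per_bin
  bins <- as.numeric(names(agg))[keep]
  new_count_series(series$fly_id, series$condition, series$monitor_id,
                   series$channel,
                   as.POSIXct(bins * bin_minutes * 60 + onset,
                              origin = "1970-01-01", tz = "UTC"),
                   as.numeric(agg[keep]), bin_minutes)
}
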