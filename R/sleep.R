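# Sleep scoring by the standard fly convention: any continuous period of
# locomotor inactivity lasting at least five minutes is sleep. Minutes are
# scored 1 (sleep) / 0 (wake) and summarised per phase, per day and per
# condition. A run of zeros touching the start or end of the recording
# counts if its observed length reaches the window (no censoring
# correction).

new_sleep_state <- function(fly_id, condition, timestamp, sleep,
                            window_minutes) {
  structure(list(fly_id = fly_id, condition = condition,
                 timestamp = timestamp, sleep = as.integer(sleep),
                 window_minutes = window_minutes),
            class = "sleep_state")
}

#' @export
print.sleep_state <- function(x, ...) {
  cat(sprintf("<sleep_state '%s'> %d min, %.1f%% asleep (window %g min)\n",
              x$fly_id, length(x$sleep), 100 * mean(x$sleep),
              x$window_minutes))
  invisible(x)
}

#' Score sleep from a beam-crossing count series
#'
#' A minute is sleep iff it lies inside a maximal run of zero-count readings
#' whose total duration is at least `window_minutes` (equivalently: a window
#' of `window_minutes` of consecutive zero readings marks all its minutes as
#' sleep; the two formulations coincide). Series recorded faster than once
#' per minute are first aggregated to 1-minute sums; intervals between 1 and
#' `window_minutes` that divide the window are scored at native resolution.
#' The result is always expanded to a 1-minute binary series.
#'
#' @param series A `count_series`.
#' @param window_minutes Minimum inactivity duration scored as sleep
#'   (default 5, the standard definition).
#' @return A `sleep_state`: minute timestamps and 0/1 sleep values.
#' @export
detect_sleep <- function(series, window_minutes = 5) {
  stopifnot(inherits(series, "count_series"), window_minutes >= 1)
  if (series$interval_minutes < 1) {
    series <- bin_series(series, 1, "sum", light_onset = 0)
  }
  step <- series$interval_minutes
  if (step > window_minutes) {
    stop(sprintf("acquisition too coarse for sleep analysis: %g-min readings cannot resolve a %g-min inactivity window",
                 step, window_minutes), call. = FALSE)
  }
  if (abs(window_minutes / step - round(window_minutes / step)) > 1e-9) {
    stop(sprintf("the %g-min sleep window is not a multiple of the %g-min interval",
                 window_minutes, step), call. = FALSE)
  }
  w_readings <- as.integer(round(window_minutes / step))
  asleep_reading <- rep(FALSE, length(series$count))
  runs <- run_lengths(series$count == 0)
  ok <- runs$length >= w_readings
  for (i in which(ok)) {
    asleep_reading[runs$start[i] + seq_len(runs$length[i]) - 1L] <- TRUE
  }
  # expand each reading to the minutes it covers
  per <- as.integer(round(step))
  minute_ts <- rep(series$timestamp, each = per) +
    rep(seq_len(per) - 1L, times = length(series$count)) * 60
  new_sleep_state(series$fly_id, series$condition, minute_ts,
                  rep(asleep_reading, each = per), window_minutes)
}

#' Per-day sleep totals split by phase
#'
#' Sums sleep minutes within each onset-anchored experimental day, split
#' into day-phase and night-phase sleep during LD. Only days with the full
#' 1440 minutes present are `complete`.
#'
#' @param state A `sleep_state` from [detect_sleep()].
#' @param calendar A [light_calendar()].
#' @return Data frame: `day`, `regime`, `complete`, `sleep_total_min`,
#'   `sleep_day_min`, `sleep_night_min` (NA outside LD).
#' @export
sleep_summary <- function(state, calendar) {
  stopifnot(inherits(state, "sleep_state"))
  lab <- label_reading(state$timestamp, calendar)
  day <- lab$experimental_day
  tot <- tapply(state$sleep, day, sum)
  n <- tapply(state$sleep, day, length)
  reg <- tapply(lab$regime, day, function(r) r[1L])
  dsl <- tapply(state$sleep * (lab$phase == "day"), day, sum)
  nsl <- tapply(state$sleep * (lab$phase == "night"), day, sum)
  is_ld <- as.character(reg) == "LD"
  data.frame(day = as.Date(names(tot)), regime = as.character(reg),
             complete = as.integer(n) == 1440L,
             sleep_total_min = as.numeric(tot),
             sleep_day_min = ifelse(is_ld, as.numeric(dsl), NA_real_),
             sleep_night_min = ifelse(is_ld, as.numeric(nsl), NA_real_),
             row.names = NULL)
}

#' Sleep profile across flies
#'
#' Mean fraction of time asleep per bin, per condition, with SEM across
#' flies. `full_experiment` runs over the whole span; `ld_average` folds
#' complete LD days onto a 24-h time-of-day axis anchored at light onset
#' (each fly averaged over its days first).
#'
#' @param states List of `sleep_state` objects (alive flies).
#' @param calendar A [light_calendar()].
#' @param bin_minutes Bin width in minutes.
#' @param mode `"full_experiment"` or `"ld_average"`.
#' @return Data frame: `condition`, `bin_start`, `mean` (sleep fraction in
#'   `[0, 1]`), `sem`, `n`.
#' @export
sleep_profile <- function(states, calendar, bin_minutes = 30,
                          mode = c("full_experiment", "ld_average")) {
  mode <- match.arg(mode)
  as_series <- lapply(states, function(st) {
    new_count_series(st$fly_id, st$condition, NA, NA,
                     st$timestamp, st$sleep, 1)
  })
  prof <- activity_profile(as_series, calendar, bin_minutes, mode)
  # activity_profile sums minutes per bin; rescale to a fraction
  prof$mean <- prof$mean / bin_minutes
  prof$sem <- prof$sem / bin_minutes
  prof
}

#' Sleep bouts per day for one fly
#'
#' A sleep bout is a maximal run of sleep minutes; by construction no bout
#' is shorter than the detection window. A bout belongs to the experimental
#' day containing its first minute.
#'
#' @param state A `sleep_state`.
#' @param calendar A [light_calendar()].
#' @return Data frame per day: `day`, `bout_count`, `mean_bout_length_min`
#'   (0 and `has_bouts = FALSE` on sleepless days), `total_bout_min`.
#' @export
sleep_bouts <- function(state, calendar) {
  stopifnot(inherits(state, "sleep_state"))
  lab <- label_reading(state$timestamp, calendar)
  runs <- run_lengths(state$sleep == 1L)
  days <- sort(unique(lab$experimental_day))
  bout_day <- lab$experimental_day[runs$start]
  out <- do.call(rbind, lapply(days, function(d) {
    l <- runs$length[bout_day == d]
    data.frame(day = d, bout_count = length(l),
               mean_bout_length_min = if (length(l)) mean(l) else 0,
               total_bout_min = sum(l), has_bouts = length(l) > 0L)
  }))
  rownames(out) <- NULL
  out
}
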