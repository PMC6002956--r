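# Locomotor-activity statistics. Aggregation is fly-level first, then
# condition-level (mean of fly means), so flies recorded for unequal numbers
# of days carry equal weight; SEM is always across individuals, not days.

#' Per-fly per-day activity table
#'
#' The central bookkeeping table behind the activity and viability outputs:
#' one row per fly per onset-anchored experimental day, with whole-day,
#' day-phase and night-phase totals (phases only in LD).
#'
#' @param series_list Named list of `count_series` (dead flies should
#'   already be excluded, see [exclude_dead()]).
#' @param calendar A [light_calendar()].
#' @return Data frame: `fly_id`, `condition`, `day`, `regime`, `complete`,
#'   `total`, `day_total`, `night_total` (NA outside LD).
#' @export
fly_day_table <- function(series_list, calendar) {
  rows <- lapply(series_list, function(s) {
    lab <- label_reading(s$timestamp, calendar)
    day <- lab$experimental_day
    full <- as.integer(round(24 * 60 / s$interval_minutes))
    tot <- tapply(s$count, day, sum)
    n <- tapply(s$count, day, length)
    reg <- tapply(lab$regime, day, function(r) r[1L])
    dsum <- tapply(s$count * (lab$phase == "day"), day, sum)
    nsum <- tapply(s$count * (lab$phase == "night"), day, sum)
    is_ld <- as.character(reg) == "LD"
    data.frame(fly_id = s$fly_id, condition = s$condition,
               day = as.Date(names(tot)), regime = as.character(reg),
               complete = as.integer(n) == full,
               total = as.numeric(tot),
               day_total = ifelse(is_ld, as.numeric(dsum), NA_real_),
               night_total = ifelse(is_ld, as.numeric(nsum), NA_real_),
               row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Condition summary of daily locomotor activity
#'
#' For each fly, averages its daily totals over the complete days of the
#' requested regime (optionally restricted to the day or night phase in LD),
#' then summarises each condition as mean, SEM and n across flies. The
#' per-fly values are returned too, for box/density plotting and external
#' statistics.
#'
#' @param fly_days Data frame from [fly_day_table()].
#' @param regime `"LD"` or `"DD"`.
#' @param phase `"all"`, `"day"` or `"night"` (phases apply to LD only).
#' @return List: `summary` (condition, mean, sem, n; `n = 0` rows keep
#'   `mean = NA` rather than erroring) and `per_fly` (fly_id, condition,
#'   mean_daily_counts).
#' @export
condition_daily_activity <- function(fly_days, regime = c("LD", "DD"),
                                     phase = c("all", "day", "night")) {
  regime <- match.arg(regime)
  phase <- match.arg(phase)
  d <- fly_days[fly_days$regime == regime & fly_days$complete, , drop = FALSE]
  col <- switch(phase, all = "total", day = "day_total",
                night = "night_total")
  per_fly <- do.call(rbind, lapply(split(d, d$fly_id), function(g) {
    data.frame(fly_id = g$fly_id[1L], condition = g$condition[1L],
               mean_daily_counts = mean(g[[col]]))
  }))
  conds <- unique(fly_days$condition)
  summary <- do.call(rbind, lapply(conds, function(cn) {
    v <- per_fly$mean_daily_counts[per_fly$condition == cn]
    data.frame(condition = cn, regime = regime, phase = phase,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = sem(v), n = length(v))
  }))
  rownames(summary) <- NULL
  if (!is.null(per_fly)) rownames(per_fly) <- NULL
  list(summary = summary, per_fly = per_fly)
}

#' Daily mean activity by experimental day
#'
#' Day-to-day changes in behaviour: for each condition and complete
#' experimental day, the mean and SEM over flies of that day's total counts.
#'
#' @param fly_days Data frame from [fly_day_table()].
#' @return Data frame: `condition`, `day`, `regime`, `mean`, `sem`, `n`.
#' @export
activity_by_day <- function(fly_days) {
  d <- fly_days[fly_days$complete, , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, list(d$condition, d$day), drop = TRUE),
    function(g) {
      data.frame(condition = g$condition[1L], day = g$day[1L],
                 regime = g$regime[1L], mean = mean(g$total),
                 sem = sem(g$total), n = nrow(g))
    }))
  out <- out[order(out$condition, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activity profile across the experiment or the average LD day
#'
#' `full_experiment` bins each fly's series (counts summed per bin, bins
#' anchored at light onset) and averages across flies per condition and bin.
#' `ld_average` additionally folds all complete LD days onto a single 24-h
#' time-of-day axis anchored at light onset, averaging each fly over its
#' days before averaging across flies.
#'
#' @param series_list Named list of `count_series` (alive flies).
#' @param calendar A [light_calendar()].
#' @param bin_minutes Profile bin width, a multiple of the interval.
#' @param mode `"full_experiment"` or `"ld_average"`.
#' @return Data frame: `condition`, `bin_start` (POSIXct for
#'   `full_experiment`; hours since light onset, 0-24, for `ld_average`),
#'   `mean`, `sem`, `n`.
#' @export
activity_profile <- function(series_list, calendar, bin_minutes = 30,
                             mode = c("full_experiment", "ld_average")) {
  mode <- match.arg(mode)
  onset <- calendar$light_onset
  if (mode == "full_experiment") {
    long <- do.call(rbind, lapply(series_list, function(s) {
      b <- bin_series(s, bin_minutes, "sum", onset)
      data.frame(condition = s$condition, bin = as.numeric(b$timestamp),
                 value = b$count)
    }))
  } else {
    long <- do.call(rbind, lapply(series_list, function(s) {
      lab <- label_reading(s$timestamp, calendar)
      days <- daily_totals(s, calendar)
      ok_days <- days$day[days$complete & days$regime == "LD"]
      if (length(ok_days) == 0L) {
        stop("no complete LD day available for the average LD profile",
             call. = FALSE)
      }
      keep <- lab$experimental_day %in% ok_days
      since_onset <- (as.numeric(s$timestamp[keep]) - onset) %% 86400
      bin <- floor(since_onset / (bin_minutes * 60))
      per_day_bin <- tapply(s$count[keep],
                            list(lab$experimental_day[keep], bin), sum)
      fly_mean <- colMeans(per_day_bin)
      data.frame(condition = s$condition,
                 bin = as.numeric(names(fly_mean)) * bin_minutes / 60,
                 value = as.numeric(fly_mean))
    }))
  }
  out <- do.call(rbind, lapply(
    split(long, list(long$condition, long$bin), drop = TRUE),
    function(g) data.frame(condition = g$condition[1L], bin_start = g$bin[1L],
                           mean = mean(g$value), sem = sem(g$value),
                           n = nrow(g))))
  if (mode == "full_experiment") {
    out$bin_start <- as.POSIXct(out$bin_start, origin = "1970-01-01",
                                tz = "UTC")
  }
  out <- out[order(out$condition, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activity bouts per day for one fly
#'
#' An activity bout is a maximal run of consecutive readings with count > 0;
#' its length is the run length times the acquisition interval. A bout
#' belongs to the experimental day containing its first reading (bouts
#' crossing the day boundary are not split).
#'
#' @param series A `count_series` at the native acquisition interval.
#' @param calendar A [light_calendar()].
#' @return Data frame with one row per experimental day present in the
#'   series: `day`, `bout_count`, `mean_bout_length_min` (0 and flagged by
#'   `has_bouts = FALSE` on all-zero days), `total_bout_min`.
#' @export
activity_bouts <- function(series, calendar) {
  stopifnot(inherits(series, "count_series"))
  lab <- label_reading(series$timestamp, calendar)
  runs <- run_lengths(series$count > 0)
  days <- sort(unique(lab$experimental_day))
  bout_day <- lab$experimental_day[runs$start]
  len_min <- runs$length * series$interval_minutes
  out <- do.call(rbind, lapply(days, function(d) {
    l <- len_min[bout_day == d]
    data.frame(day = d, bout_count = length(l),
               mean_bout_length_min = if (length(l)) mean(l) else 0,
               total_bout_min = sum(l), has_bouts = length(l) > 0L)
  }))
  rownames(out) <- NULL
  out
}
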