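# Automatic dead-fly exclusion: a fly whose total beam crossings fall below
# a daily threshold on any complete experimental day is treated as dead and
# excluded from all downstream statistics. This replaces manual inspection
# of actograms for flatlined channels.

#' Per-day activity totals for one fly
#'
#' Sums beam crossings over onset-anchored experimental days. Days with
#' fewer readings than a full 24 h span (the partial first/last day of a
#' recording) are flagged `complete = FALSE` and never used for death calls,
#' since their totals are biased low.
#'
#' @param series A `count_series`.
#' @param calendar A [light_calendar()].
#' @return Data frame: `day` (Date), `regime`, `total`, `n_readings`,
#'   `complete`.
#' @export
daily_totals <- function(series, calendar) {
  stopifnot(inherits(series, "count_series"), length(series$count) > 0L)
  lab <- label_reading(series$timestamp, calendar)
  day <- lab$experimental_day
  tot <- tapply(series$count, day, sum)
  n <- tapply(series$count, day, length)
  reg <- tapply(lab$regime, day, function(r) r[1L])
  full <- as.integer(round(24 * 60 / series$interval_minutes))
  data.frame(day = as.Date(names(tot)), regime = as.character(reg),
             total = as.numeric(tot), n_readings = as.integer(n),
             complete = as.integer(n) == full, row.names = NULL)
}

#' Death call for one fly from its daily totals
#'
#' A fly is dead iff its total counts fall strictly below `threshold` on any
#' complete experimental day; the first such day is reported. With
#' `mode = "exclude"` (default) the whole fly is excluded from analysis;
#' `mode = "truncate"` keeps the days before the first sub-threshold day.
#'
#' @param daily Data frame from [daily_totals()].
#' @param threshold Counts/day; `0` can never kill a fly (`0 < 0` is false).
#' @param mode Whole-fly exclusion (`"exclude"`) or pre-death retention
#'   (`"truncate"`).
#' @return List: `alive` (logical), `first_dead_day` (Date or `NA`),
#'   `min_daily_total` (over complete days), `mode`.
#' @export
flag_dead <- function(daily, threshold, mode = c("exclude", "truncate")) {
  mode <- match.arg(mode)
  cd <- daily[daily$complete, , drop = FALSE]
  if (nrow(cd) == 0L) {
    stop("no complete experimental day; cannot assess viability", call. = FALSE)
  }
  below <- which(cd$total < threshold)
  list(alive = length(below) == 0L,
       first_dead_day = if (length(below)) cd$day[below[1L]] else as.Date(NA),
       min_daily_total = min(cd$total),
       mode = mode)
}

#' Viability report over all flies of an experiment
#'
#' Applies [daily_totals()] + [flag_dead()] to every fly and tabulates dead
#' flies per condition. The condition table reconciles:
#' `n_assigned = n_dead + n_analyzed`.
#'
#' @param series_list Named list of `count_series` from
#'   [extract_fly_series()].
#' @param layout An [experiment_layout()] (supplies calendar and threshold).
#' @param mode Passed to [flag_dead()].
#' @return List with `flies` (fly_id, condition, alive, first_dead_day,
#'   min_daily_total) and `conditions` (condition, n_assigned, n_dead,
#'   n_analyzed) data frames.
#' @export
viability_report <- function(series_list, layout,
                             mode = c("exclude", "truncate")) {
  mode <- match.arg(mode)
  rows <- lapply(series_list, function(s) {
    fd <- flag_dead(daily_totals(s, layout$calendar),
                    layout$dead_threshold, mode)
    data.frame(fly_id = s$fly_id, condition = s$condition,
               alive = fd$alive, first_dead_day = fd$first_dead_day,
               min_daily_total = fd$min_daily_total)
  })
  flies <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  conds <- do.call(rbind, lapply(split(flies, flies$condition), function(g) {
    data.frame(condition = g$condition[1L], n_assigned = nrow(g),
               n_dead = sum(!g$alive), n_analyzed = sum(g$alive))
  }))
  rownames(conds) <- NULL
  list(flies = flies, conditions = conds)
}

#' Drop dead flies from a series list
#'
#' @param series_list Named list of `count_series`.
#' @param report A [viability_report()].
#' @return The sublist of series whose flies are alive.
#' @export
exclude_dead <- function(series_list, report) {
  keep <- report$flies$fly_id[report$flies$alive]
  series_list[names(series_list) %in% keep]
}
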