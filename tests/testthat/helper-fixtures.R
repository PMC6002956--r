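# Fixture builders and independent oracles. Everything is generated in
# code; no binary fixtures.

# a calendar with 3 LD days then 6 DD days, onset 06:00
fix_calendar <- function(ld_days = 3, dd_days = 6, onset = "06:00") {
  d0 <- as.Date("2017-01-01")
  ld <- if (ld_days > 0) c(d0, d0 + ld_days - 1) else c(NULL, NULL)
  dd0 <- d0 + ld_days
  light_calendar(
    ld_start = if (ld_days > 0) d0 else NULL,
    ld_end = if (ld_days > 0) d0 + ld_days - 1 else NULL,
    dd_start = if (dd_days > 0) dd0 else NULL,
    dd_end = if (dd_days > 0) dd0 + dd_days - 1 else NULL,
    light_onset = onset)
}

# series starting exactly at light onset of the calendar's first day
fix_series <- function(count, interval = 1, calendar = fix_calendar(),
                       fly_id = "fly", condition = "cond") {
  d0 <- min(do.call(c, Filter(Negate(is.null),
                              list(calendar$ld_dates[1],
                                   calendar$dd_dates[1]))))
  count_series(count, interval,
               start = as.POSIXct(d0, tz = "UTC") + calendar$light_onset,
               fly_id = fly_id, condition = condition)
}

# hand-rolled monitor-file line in the 42-field dialect
monitor_line <- function(index, date, time, status = 1, counts = rep(0, 32),
                         light = 0) {
  paste(c(index, date, time, status, rep(0, 5), light, counts),
        collapse = "\t")
}

write_fixture_monitor <- function(path, n_rows = 3, start_min = 0,
                                  counts = NULL, status = rep(1, n_rows)) {
  if (is.null(counts)) counts <- matrix(1, n_rows, 32)
  lines <- vapply(seq_len(n_rows), function(i) {
    mins <- start_min + i - 1
    monitor_line(i, "1 Jan 17",
                 sprintf("%02d:%02d:00", mins %/% 60, mins %% 60),
                 status = status[i], counts = counts[i, ])
  }, character(1))
  writeLines(lines, path)
  path
}

# independent sliding-window sleep oracle: every window of w consecutive
# zero readings marks all its minutes as sleep
sleep_oracle_sliding <- function(x, w = 5) {
  n <- length(x)
  s <- rep(FALSE, n)
  if (n >= w) {
    for (i in 1:(n - w + 1)) {
      if (all(x[i:(i + w - 1)] == 0)) s[i:(i + w - 1)] <- TRUE
    }
  }
  as.integer(s)
}

# independent brute-force chi-square periodogram: explicit column loop
csp_oracle <- function(x, periods_bins) {
  vapply(periods_bins, function(p) {
    K <- length(x) %/% p
    xx <- x[seq_len(K * p)]
    M <- mean(xx)
    Mh <- numeric(p)
    for (h in seq_len(p)) {
      v <- 0
      for (k in seq_len(K)) v <- v + xx[(k - 1) * p + h]
      Mh[h] <- v / K
    }
    denom <- sum((xx - M)^2)
    if (denom == 0) 0 else K * length(xx) * sum((Mh - M)^2) / denom
  }, numeric(1))
}

# brute-force bout scan: lengths of maximal positive runs
bout_oracle <- function(active) {
  lens <- integer(0)
  cur <- 0L
  for (v in active) {
    if (v) cur <- cur + 1L
    else if (cur > 0L) { lens <- c(lens, cur); cur <- 0L }
  }
  if (cur > 0L) lens <- c(lens, cur)
  lens
}
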