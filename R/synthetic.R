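# Seeded generator of synthetic DAM monitor data with per-fly ground truth.
# Beam crossings are event counts, so counts are drawn as
# Poisson(rate(t) * interval); the square waveform is the default companion
# for periodogram tests because its folded profile is maximally crisp.
# Identical (specs, calendar, seed) input yields byte-identical files.

#' Specification of one synthetic fly
#'
#' Defines the deterministic rate function `rate(t) = max(0, baseline +
#' amplitude * w(t))` (counts/min) from which a channel's Poisson counts are
#' drawn. `w(t)` is a unit waveform with period `period_h` and phase
#' `phase_h` relative to the first light onset: a sinusoid, a square wave
#' (1 during the first half of each cycle, 0 otherwise), or a crepuscular
#' bimodal profile (Gaussian bumps, sd 1 h, at the cycle start and
#' midpoint). During LD days the rate is additionally masked:
#' multiplied by `2 * day_active_fraction` in the day phase and
#' `2 * (1 - day_active_fraction)` at night (0.5 = no masking). From the
#' light onset of `death_day` onward the rate is identically zero.
#'
#' @param fly_id Identifier used in the ground-truth table.
#' @param baseline_rate Baseline rate, counts/min.
#' @param amplitude Waveform amplitude, counts/min.
#' @param period_h,phase_h Waveform period and phase, hours.
#' @param waveform `"square"`, `"sinusoid"` or `"crepuscular"`.
#' @param death_day Date from whose light onset the fly is dead, or `NULL`.
#' @param day_active_fraction LD masking weight in `[0, 1]`.
#' @return A `fly_spec` object.
#' @export
fly_spec <- function(fly_id, baseline_rate = 0, amplitude = 0,
                     period_h = 24, phase_h = 0,
                     waveform = c("square", "sinusoid", "crepuscular"),
                     death_day = NULL, day_active_fraction = 0.5) {
  waveform <- match.arg(waveform)
  if (baseline_rate < 0 || period_h <= 0 ||
      day_active_fraction < 0 || day_active_fraction > 1) {
    stop("invalid fly spec: rates must be non-negative, period positive, day_active_fraction in [0, 1]",
         call. = FALSE)
  }
  structure(list(fly_id = fly_id, baseline_rate = baseline_rate,
                 amplitude = amplitude, period_h = period_h,
                 phase_h = phase_h, waveform = waveform,
                 death_day = if (is.null(death_day)) NULL
                             else as.Date(death_day),
                 day_active_fraction = day_active_fraction),
            class = "fly_spec")
}

# rate in counts/min at each timestamp
spec_rate <- function(spec, t, calendar) {
  h <- (as.numeric(t) - (as.numeric(as.POSIXct(
    calendar_dates(calendar)[1L], tz = "UTC")) +
    calendar$light_onset)) / 3600
  ph <- ((h - spec$phase_h) %% spec$period_h)
  w <- switch(spec$waveform,
    square = as.numeric(ph < spec$period_h / 2),
    sinusoid = sin(2 * pi * ph / spec$period_h),
    crepuscular = {
      d1 <- pmin(ph, spec$period_h - ph)
      d2 <- abs(ph - spec$period_h / 2)
      exp(-(d1 / 1)^2 / 2) + exp(-(d2 / 1)^2 / 2)
    })
  rate <- pmax(0, spec$baseline_rate + spec$amplitude * w)
  lab <- label_reading(t, calendar)
  mask <- rep(1, length(t))
  mask[lab$phase == "day"] <- 2 * spec$day_active_fraction
  mask[lab$phase == "night"] <- 2 * (1 - spec$day_active_fraction)
  rate <- rate * mask
  if (!is.null(spec$death_day)) {
    rate[lab$experimental_day >= spec$death_day] <- 0
  }
  rate
}

#' Generate a synthetic 32-channel monitor with ground truth
#'
#' Produces a `dam_monitor` covering every experimental day of the calendar
#' (readings from the first light onset to the last day's next onset) whose
#' counts are Poisson draws from each fly's programmed rate, plus a
#' ground-truth table sufficient to score parameter-recovery tests. Fewer
#' than 32 specs are padded with zero-rate (empty-channel) specs.
#'
#' @param specs List of up to 32 [fly_spec()] objects, channel order.
#' @param calendar A [light_calendar()] (its LD/DD dates set the span).
#' @param interval_minutes Acquisition interval of the synthetic recording.
#' @param seed Integer seed; fixes the file bytes completely.
#' @param monitor_id Monitor identifier.
#' @return List with `monitor` (a `dam_monitor`) and `truth` (data frame:
#'   `fly_id`, `channel`, `period_h`, `death_day`, `expected_daily_counts`,
#'   `baseline_rate`, `amplitude`, `waveform`).
#' @export
generate_monitor <- function(specs, calendar, interval_minutes = 1, seed = 1,
                             monitor_id = "M1") {
  stopifnot(inherits(calendar, "light_calendar"),
            length(specs) >= 1L, length(specs) <= DAM_N_CHANNELS,
            interval_minutes > 0)
  for (s in specs) stopifnot(inherits(s, "fly_spec"))
  n_pad <- DAM_N_CHANNELS - length(specs)
  if (n_pad > 0L) {
    specs <- c(specs, lapply(seq_len(n_pad), function(i) {
      fly_spec(sprintf("empty_%02d", length(specs) + i))
    }))
  }
  dates <- calendar_dates(calendar)
  first <- dates[1L]
  last <- dates[length(dates)]
  n_days <- as.integer(last - first) + 1L
  start <- as.POSIXct(first, tz = "UTC") + calendar$light_onset
  n <- as.integer(round(n_days * 24 * 60 / interval_minutes))
  ts <- start + (seq_len(n) - 1L) * interval_minutes * 60
  cnt <- matrix(0L, n, DAM_N_CHANNELS)
  truth <- vector("list", DAM_N_CHANNELS)
  set.seed(as.integer(seed))
  for (ch in seq_len(DAM_N_CHANNELS)) {
    sp <- specs[[ch]]
    lambda <- spec_rate(sp, ts, calendar) * interval_minutes
    cnt[, ch] <- stats::rpois(n, lambda)
    truth[[ch]] <- data.frame(
      fly_id = sp$fly_id, channel = ch, period_h = sp$period_h,
      death_day = if (is.null(sp$death_day)) as.Date(NA) else sp$death_day,
      expected_daily_counts = sum(lambda) / n_days,
      baseline_rate = sp$baseline_rate, amplitude = sp$amplitude,
      waveform = sp$waveform)
  }
  lab <- label_reading(ts, calendar)
  records <- data.frame(reading_index = seq_len(n), timestamp = ts,
                        status_code = 1L,
                        light_sensor = as.integer(lab$phase == "day"))
  mon <- new_dam_monitor(monitor_id, interval_minutes, records,
                         matrix(0L, n, 5L), cnt, empty_issues(),
                         n_rows_in = n)
  list(monitor = mon,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Inject controlled defects into a monitor
#'
#' Corrupts a clean `dam_monitor` deterministically, for exercising the
#' validator: `n_bad_status` rows get status code 51 (hardware error) and
#' `n_gaps` runs of `gap_len` consecutive rows are deleted (timestamp
#' gaps). The first and last rows are never touched, and defects never
#' overlap, so each injected defect maps to exactly one validation issue.
#'
#' @param data A `dam_monitor`.
#' @param n_bad_status Number of rows to mark with a bad status code.
#' @param n_gaps Number of gaps to cut.
#' @param gap_len Rows removed per gap.
#' @param seed Integer seed for defect placement.
#' @return List with `monitor` (corrupted) and `defects` (data frame:
#'   `kind`, `row` — row numbers refer to the corrupted file as written).
#' @export
inject_errors <- function(data, n_bad_status = 0, n_gaps = 0, gap_len = 1,
                          seed = 1) {
  stopifnot(inherits(data, "dam_monitor"))
  n <- nrow(data$records)
  stopifnot(n_bad_status + n_gaps * gap_len <= n - 2L)
  set.seed(as.integer(seed))
  # choose non-adjacent anchor rows in 2..n-1 so defects stay distinct
  need <- n_bad_status + n_gaps
  cand <- seq(2L, n - 1L - gap_len)
  anchors <- integer(0)
  while (length(anchors) < need && length(cand) > 0L) {
    a <- cand[sample.int(length(cand), 1L)]
    anchors <- c(anchors, a)
    cand <- cand[abs(cand - a) > gap_len + 1L]
  }
  if (length(anchors) < need) {
    stop("series too short to place the requested defects without overlap",
         call. = FALSE)
  }
  bad_rows <- sort(anchors[seq_len(n_bad_status)])
  gap_rows <- sort(anchors[n_bad_status + seq_len(n_gaps)])
  data$records$status_code[bad_rows] <- 51L
  drop <- unlist(lapply(gap_rows, function(g) g + seq_len(gap_len) - 1L))
  if (length(drop) > 0L) {
    data$records <- data$records[-drop, , drop = FALSE]
    data$counts <- data$counts[-drop, , drop = FALSE]
    data$extras <- data$extras[-drop, , drop = FALSE]
    rownames(data$records) <- NULL
  }
  # defect locations in the corrupted row numbering
  shift <- function(r) r - vapply(r, function(x) sum(drop < x), integer(1))
  defects <- rbind(
    if (n_bad_status > 0)
      data.frame(kind = "bad_status_code", row = shift(bad_rows)),
    if (n_gaps > 0)
      data.frame(kind = "timestamp_gap", row = shift(gap_rows)))
  list(monitor = data, defects = defects)
}
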