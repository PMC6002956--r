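# Free-running circadian period estimation by the chi-square periodogram
# (Sokolove-Bushell), with a significance-referenced rhythmicity filter,
# plus actogram matrix construction (single or double plotted).
#
# For a candidate period of p bins the series is folded into K complete
# cycles (K = floor(N/p); the ragged last cycle is discarded) and
#   Q(p) = K * N' * sum_h (M_h - M)^2 / sum_i (x_i - M)^2
# with N' = K*p, M_h the column (phase) means and M the grand mean over the
# N' points used. Q is compared to a chi-square upper quantile with p - 1
# degrees of freedom; because one line is drawn per tested period, the
# default quantile is Sidak-corrected across the m tested periods,
# (1 - alpha)^(1/m), so the family-wise false-rhythm rate stays near alpha.

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

# Largest bin width (minutes) that divides every tested period and is a
# multiple of the acquisition interval; NULL if none exists.
periodogram_bin <- function(min_h, resolution_h, interval_minutes,
                            max_bin = 60L) {
  m0 <- min_h * 60
  r0 <- resolution_h * 60
  if (abs(m0 - round(m0)) > 1e-9 || abs(r0 - round(r0)) > 1e-9) return(NULL)
  g <- gcd2(as.integer(round(m0)), as.integer(round(r0)))
  divs <- which(g %% seq_len(min(g, max_bin)) == 0L)
  ok <- divs[divs %% interval_minutes == 0 |
               abs(divs / interval_minutes -
                     round(divs / interval_minutes)) < 1e-9]
  if (length(ok) == 0L) return(NULL)
  max(ok)
}

#' Chi-square periodogram of a count series
#'
#' Estimates the free-running circadian period of one fly by folding its
#' beam-crossing series at every candidate period in `period_range` (spacing
#' `resolution_h`) and scoring the between-phase variance against the total
#' variance (Sokolove-Bushell Q statistic). Each Q is compared to a
#' chi-square significance line; the peak is the period maximising the
#' excess `Q - S` (ties broken toward the shorter period), and the rhythm
#' strength is `Q(peak) / S(peak)`. A fly is rhythmic iff the strength
#' reaches `strength_threshold`.
#'
#' The series is first binned to a width that makes every tested period an
#' integer number of bins (largest such divisor, at most one hour); a
#' resolution not representable on the acquisition grid is an error with a
#' suggested alternative. Free-running periodicity is a property of constant
#' darkness, so when a calendar is supplied the series is restricted to DD
#' days (set `use_regime = "LD"` to override, with a warning).
#'
#' @param series A `count_series`.
#' @param period_range Tested period range in hours, `c(min, max)`.
#' @param resolution_h Spacing of tested periods, hours.
#' @param alpha Significance level of the chi-square line.
#' @param correction Multiple-testing handling for the line across tested
#'   periods: `"sidak"` (default), `"bonferroni"`, or `"none"` (pointwise).
#' @param strength_threshold Minimum `Q(peak)/S(peak)` to call a fly
#'   rhythmic (default 1 = peak reaches its significance line).
#' @param bin_minutes Fold bin width; `NULL` (default) chooses it
#'   automatically.
#' @param calendar Optional [light_calendar()] used to restrict the series
#'   to one regime.
#' @param use_regime Regime analysed when `calendar` is given (`"DD"`;
#'   `"LD"` emits a warning).
#' @param min_cycles Minimum number of cycles of the longest tested period
#'   that must be present.
#' @return A `periodogram` object: `table` (period_h, p_bins, Q, S),
#'   `peak_period` (hours, NA for a flat series), `rhythm_strength`,
#'   `rhythmic`, plus the settings used.
#' @export
chi_square_periodogram <- function(series, period_range = c(18, 30),
                                   resolution_h = 0.1, alpha = 0.05,
                                   correction = c("sidak", "bonferroni",
                                                  "none"),
                                   strength_threshold = 1,
                                   bin_minutes = NULL, calendar = NULL,
                                   use_regime = c("DD", "LD"),
                                   min_cycles = 3) {
  correction <- match.arg(correction)
  use_regime <- match.arg(use_regime)
  stopifnot(inherits(series, "count_series"),
            length(period_range) == 2L, period_range[1L] < period_range[2L],
            resolution_h > 0, alpha > 0, alpha < 1)
  if (!is.null(calendar)) {
    if (use_regime == "LD") {
      warning("periodogram computed on LD days: entrained rhythms reflect the light cycle, not the free-running period",
              call. = FALSE)
    }
    lab <- label_reading(series$timestamp, calendar)
    keep <- lab$regime == use_regime
    series <- new_count_series(series$fly_id, series$condition,
                               series$monitor_id, series$channel,
                               series$timestamp[keep], series$count[keep],
                               series$interval_minutes)
  }
  if (is.null(bin_minutes)) {
    bin_minutes <- periodogram_bin(period_range[1L], resolution_h,
                                   series$interval_minutes)
    if (is.null(bin_minutes)) {
      stop(sprintf("tested periods cannot be placed on the %g-min acquisition grid; use a resolution that is a multiple of %g h",
                   series$interval_minutes, series$interval_minutes / 60),
           call. = FALSE)
    }
  }
  periods <- seq(period_range[1L], period_range[2L], by = resolution_h)
  p_bins <- periods * 60 / bin_minutes
  if (any(abs(p_bins - round(p_bins)) > 1e-9)) {
    stop(sprintf("a %g-min fold bin does not represent every tested period as a whole number of bins; adjust bin_minutes or resolution",
                 bin_minutes), call. = FALSE)
  }
  p_bins <- as.integer(round(p_bins))
  binned <- bin_series(series, bin_minutes, "sum", light_onset = 0)
  x <- binned$count
  n <- length(x)
  span_h <- n * bin_minutes / 60
  if (span_h < min_cycles * period_range[2L]) {
    stop(sprintf("series spans %.1f h but %g cycles of the longest tested period (%g h) require %.1f h",
                 span_h, min_cycles, period_range[2L],
                 min_cycles * period_range[2L]), call. = FALSE)
  }
  m <- length(periods)
  level <- switch(correction,
                  sidak = (1 - alpha)^(1 / m),
                  bonferroni = 1 - alpha / m,
                  none = 1 - alpha)
  Q <- numeric(m)
  flat <- stats::var(x) == 0
  for (j in seq_len(m)) {
    p <- p_bins[j]
    K <- n %/% p
    xx <- x[seq_len(K * p)]
    M <- mean(xx)
    denom <- sum((xx - M)^2)
    if (denom == 0) { Q[j] <- 0; next }
    Mh <- colMeans(matrix(xx, nrow = K, byrow = TRUE))
    Q[j] <- K * length(xx) * sum((Mh - M)^2) / denom
  }
  S <- stats::qchisq(level, df = p_bins - 1L)
  tab <- data.frame(period_h = periods, p_bins = p_bins, Q = Q, S = S)
  if (flat) {
    peak <- NA_real_; strength <- 0; rhythmic <- FALSE
  } else {
    i <- which.max(Q - S)
    peak <- periods[i]
    strength <- Q[i] / S[i]
    rhythmic <- strength >= strength_threshold
  }
  structure(list(fly_id = series$fly_id, condition = series$condition,
                 table = tab, peak_period = peak,
                 rhythm_strength = strength, rhythmic = rhythmic,
                 alpha = alpha, correction = correction,
                 strength_threshold = strength_threshold,
                 bin_minutes = bin_minutes),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram '%s'> peak %s h, strength %.2f, %s\n",
              x$fly_id,
              if (is.na(x$peak_period)) "NA" else format(x$peak_period),
              x$rhythm_strength,
              if (x$rhythmic) "rhythmic" else "arrhythmic"))
  invisible(x)
}

#' Partition flies into rhythmic and arrhythmic sets
#'
#' Splits periodogram results by rhythm strength (peak Q over its
#' significance line); the threshold is inclusive. Downstream period box
#' plots and mean periodograms should use the rhythmic set only.
#'
#' @param results List of `periodogram` objects.
#' @param strength_threshold Minimum strength for the rhythmic set.
#' @return List with `rhythmic` and `arrhythmic` sublists.
#' @export
filter_arrhythmic <- function(results, strength_threshold = 1) {
  s <- vapply(results, function(r) r$rhythm_strength, numeric(1))
  list(rhythmic = results[s >= strength_threshold],
       arrhythmic = results[s < strength_threshold])
}

#' Mean periodogram across flies
#'
#' Pointwise mean and SEM of the Q statistic across flies sharing one
#' period grid (typically the rhythmic set of a condition).
#'
#' @param results Non-empty list of `periodogram` objects on identical
#'   grids.
#' @return Data frame: `period_h`, `mean_Q`, `sem_Q`, `n`.
#' @export
aggregate_periodogram <- function(results) {
  stopifnot(length(results) >= 1L)
  grid <- results[[1L]]$table$period_h
  for (r in results) {
    if (length(r$table$period_h) != length(grid) ||
        any(r$table$period_h != grid)) {
      stop("periodograms were computed on different period grids and cannot be averaged",
           call. = FALSE)
    }
  }
  qm <- vapply(results, function(r) r$table$Q, numeric(length(grid)))
  qm <- matrix(qm, nrow = length(grid))
  data.frame(period_h = grid, mean_Q = rowMeans(qm),
             sem_Q = apply(qm, 1L, sem), n = length(results))
}

#' Actogram matrix for one fly or a condition aggregate
#'
#' Builds the raster behind an actogram: one row per onset-anchored
#' experimental day, one column per time-of-day bin. With `style =
#' "double"`, row d shows day d followed by day d+1 (twice the width), the
#' classic convention for spotting rhythms that drift across midnight; the
#' last row's right half is NA.
#'
#' @param series_list A single `count_series` or a list of them.
#' @param calendar A [light_calendar()].
#' @param bin_minutes Column width in minutes (must divide 24 h).
#' @param style `"single"` or `"double"` plotted.
#' @param stat For a list of flies: `"mean"` or `"median"` across flies per
#'   (day, bin) cell; ignored for a single fly.
#' @return An `actogram` object: `matrix` (rows named by day, columns by
#'   hours since light onset), `days`, `bin_minutes`, `style`, `tag`.
#' @export
build_actogram <- function(series_list, calendar, bin_minutes = 30,
                           style = c("single", "double"),
                           stat = c("mean", "median")) {
  style <- match.arg(style)
  stat <- match.arg(stat)
  if (inherits(series_list, "count_series")) {
    series_list <- list(series_list)
    tag <- series_list[[1L]]$fly_id
  } else {
    tag <- if (length(series_list) == 1L) series_list[[1L]]$fly_id else stat
  }
  nb <- 24 * 60 / bin_minutes
  if (abs(nb - round(nb)) > 1e-9) {
    stop("bin_minutes must divide 24 hours", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  onset <- calendar$light_onset
  long <- do.call(rbind, lapply(series_list, function(s) {
    b <- bin_series(s, bin_minutes, "sum", onset)
    lab <- label_reading(b$timestamp, calendar)
    since_onset <- (as.numeric(b$timestamp) - onset) %% 86400
    data.frame(day = lab$experimental_day,
               bin = as.integer(since_onset %/% (bin_minutes * 60)),
               value = b$count)
  }))
  agg <- tapply(long$value, list(as.character(long$day), long$bin),
                if (stat == "mean") mean else stats::median)
  days <- sort(as.Date(rownames(agg)))
  mat <- matrix(NA_real_, length(days), nb,
                dimnames = list(as.character(days),
                                sprintf("%g", (0:(nb - 1L)) * bin_minutes / 60)))
  mat[match(rownames(agg), as.character(days)),
      as.integer(colnames(agg)) + 1L] <- agg
  if (style == "double") {
    nxt <- rbind(mat[-1L, , drop = FALSE],
                 matrix(NA_real_, 1L, nb,
                        dimnames = list(NULL, colnames(mat))))
    mat <- cbind(mat, nxt)
    colnames(mat) <- sprintf("%g", (0:(2L * nb - 1L)) * bin_minutes / 60)
  }
  structure(list(matrix = mat, days = days, bin_minutes = bin_minutes,
                 style = style, tag = tag),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram '%s'> %d day(s) x %d bin(s), %s plotted\n",
              x$tag, nrow(x$matrix), ncol(x$matrix), x$style))
  invisible(x)
}
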