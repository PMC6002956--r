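# Internal helpers shared across modules. All timestamps are POSIXct in UTC:
# DAM files carry wall-clock time with no zone, and UTC avoids DST arithmetic.

.MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' @keywords internal
#' @noRd
dam_parse_datetime <- function(date_str, time_str) {
  # "D Mon YY" + "HH:MM:SS", English month abbreviations, locale-independent.
  dparts <- strsplit(trimws(date_str), "[[:space:]]+")
  tparts <- strsplit(trimws(time_str), ":", fixed = TRUE)
  n <- length(date_str)
  out <- rep(as.POSIXct(NA, tz = "UTC"), n)
  for (i in seq_len(n)) {
    dp <- dparts[[i]]
    tp <- tparts[[i]]
    if (length(dp) != 3L || length(tp) != 3L) next
    mon <- match(dp[2L], .MONTHS)
    day <- suppressWarnings(as.integer(dp[1L]))
    yy <- suppressWarnings(as.integer(dp[3L]))
    hms <- suppressWarnings(as.integer(tp))
    if (is.na(mon) || is.na(day) || is.na(yy) || anyNA(hms)) next
    if (hms[1L] > 23L || hms[2L] > 59L || hms[3L] > 59L) next
    year <- if (yy < 100L) 2000L + yy else yy
    d <- as.Date(sprintf("%04d-%02d-%02d", year, mon, day))
    if (is.na(d)) next
    out[i] <- as.POSIXct(d, tz = "UTC") +
      hms[1L] * 3600 + hms[2L] * 60 + hms[3L]
  }
  out
}

#' @keywords internal
#' @noRd
dam_format_datetime <- function(t) {
  # inverse of dam_parse_datetime: "D Mon YY" (day unpadded) and "HH:MM:SS"
  lt <- as.POSIXlt(t, tz = "UTC")
  list(
    date = sprintf("%d %s %02d", lt$mday, .MONTHS[lt$mon + 1L],
                   (lt$year + 1900L) %% 100L),
    time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, floor(lt$sec))
  )
}

#' @keywords internal
#' @noRd
parse_time_of_day <- function(x) {
  # "HH:MM" or "HH:MM:SS" -> seconds since midnight
  if (is.numeric(x)) return(as.numeric(x))
  p <- suppressWarnings(as.integer(strsplit(x, ":", fixed = TRUE)[[1L]]))
  if (length(p) == 2L) p <- c(p, 0L)
  if (length(p) != 3L || anyNA(p)) {
    stop("cannot parse time of day: ", x, call. = FALSE)
  }
  p[1L] * 3600 + p[2L] * 60 + p[3L]
}

# SEM across individuals; NA for n < 2 (a single fly carries no
# between-individual spread).
#' @keywords internal
#' @noRd
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @keywords internal
#' @noRd
run_lengths <- function(flag) {
  # maximal runs of TRUE: start index and length of each
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], length = r$lengths[keep])
}
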