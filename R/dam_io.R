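# Reading, validating and writing TriKinetics DAMSystem3 monitor files.
#
# Monitor-file dialect (fixed by this package): 42 tab-separated fields per
# row — field 1 reading index; field 2 date "D Mon YY" (English month
# abbreviations, two-digit years mapped to 2000-2099); field 3 time
# "HH:MM:SS"; field 4 status code; fields 5-9 device extras (parsed, kept,
# otherwise ignored); field 10 light-sensor 0/1; fields 11-42 beam-crossing
# counts for channels 1-32. ASCII/UTF-8, LF or CRLF.

DAM_N_FIELDS <- 42L
DAM_N_CHANNELS <- 32L

new_issue <- function(severity, kind, monitor_id, row, message) {
  data.frame(severity = severity, kind = kind, monitor_id = monitor_id,
             row = as.integer(row), message = message,
             stringsAsFactors = FALSE)
}

empty_issues <- function() {
  new_issue(character(), character(), character(), integer(), character())
}

dam_stop_issues <- function(issues, monitor_id) {
  fatal <- issues[issues$severity == "fatal", , drop = FALSE]
  msg <- sprintf(
    "monitor '%s' rejected: %d fatal issue(s), e.g. [%s row %s] %s",
    monitor_id, nrow(fatal), fatal$kind[1L],
    ifelse(is.na(fatal$row[1L]), "-", fatal$row[1L]), fatal$message[1L])
  cond <- structure(
    class = c("dam_io_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L), issues = issues))
  stop(cond)
}

new_dam_monitor <- function(monitor_id, interval_minutes, records, extras,
                            counts, issues,
                            n_rows_in = nrow(records), n_dropped = 0L,
                            n_inserted = 0L) {
  structure(list(
    monitor_id = monitor_id,
    interval_minutes = interval_minutes,
    records = records,
    extras = extras,
    counts = counts,
    issues = issues,
    n_rows_in = as.integer(n_rows_in),
    n_dropped = as.integer(n_dropped),
    n_inserted = as.integer(n_inserted)
  ), class = "dam_monitor")
}

#' @export
print.dam_monitor <- function(x, ...) {
  cat(sprintf(
    "<dam_monitor '%s'> %d records @ %g min, %s .. %s, %d issue(s)\n",
    x$monitor_id, nrow(x$records), x$interval_minutes,
    format(min(x$records$timestamp)), format(max(x$records$timestamp)),
    nrow(x$issues)))
  invisible(x)
}

# Core parser shared by read_monitor_file() and validate_monitor_file().
# Returns list(monitor = dam_monitor or NULL, issues, fatal = logical).
parse_monitor_lines <- function(lines, monitor_id, interval_minutes,
                                accepted_status = c(0L, 1L), max_gap = 6L) {
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  issues <- empty_issues()
  if (length(lines) == 0L) {
    issues <- rbind(issues, new_issue(
      "fatal", "malformed_row", monitor_id, NA,
      "file contains no data rows; supply a non-empty monitor file"))
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_cols <- which(nf != DAM_N_FIELDS)
  for (i in bad_cols) {
    issues <- rbind(issues, new_issue(
      "fatal", "wrong_column_count", monitor_id, i,
      sprintf("row has %d tab-separated fields, expected %d; check for stray tabs or truncation",
              nf[i], DAM_N_FIELDS)))
  }
  ok <- setdiff(seq_along(lines), bad_cols)
  if (length(ok) == 0L) {
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }
  m <- do.call(rbind, fields[ok])
  ts <- dam_parse_datetime(m[, 2L], m[, 3L])
  for (i in which(is.na(ts))) {
    issues <- rbind(issues, new_issue(
      "fatal", "malformed_row", monitor_id, ok[i],
      sprintf("unparseable date/time '%s %s'; expected 'D Mon YY' and 'HH:MM:SS'",
              m[i, 2L], m[i, 3L])))
  }
  idx <- suppressWarnings(as.integer(m[, 1L]))
  status <- suppressWarnings(as.integer(m[, 4L]))
  light <- suppressWarnings(as.integer(m[, 10L]))
  extras <- suppressWarnings(matrix(as.integer(m[, 5:9]), ncol = 5L))
  cnt <- suppressWarnings(matrix(as.numeric(m[, 11:42]), ncol = DAM_N_CHANNELS))
  bad_num <- which(apply(cnt, 1L, anyNA) | is.na(status))
  for (i in bad_num) {
    issues <- rbind(issues, new_issue(
      "fatal", "malformed_row", monitor_id, ok[i],
      "non-numeric status or count field; check the row for corruption"))
  }
  neg <- which(apply(cnt, 1L, function(r) any(!is.na(r) & r < 0)))
  for (i in neg) {
    issues <- rbind(issues, new_issue(
      "fatal", "negative_count", monitor_id, ok[i],
      "negative beam-crossing count; counts must be non-negative integers"))
  }
  if (any(issues$severity == "fatal")) {
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }

  # timestamp grid checks run on the full parsed timeline (bad-status rows
  # still present, so hardware-error rows do not masquerade as gaps)
  dt <- as.numeric(diff(ts), units = "mins")
  step <- interval_minutes
  dup <- which(dt <= 0)
  for (i in dup) {
    issues <- rbind(issues, new_issue(
      "fatal",
      if (dt[i] == 0) "duplicate_timestamp" else "interval_mismatch",
      monitor_id, ok[i + 1L],
      if (dt[i] == 0) "duplicate timestamp; remove the repeated reading"
      else "timestamps decrease; sort or re-export the file"))
  }
  off_grid <- which(dt > 0 & abs(dt / step - round(dt / step)) > 1e-9)
  for (i in off_grid) {
    issues <- rbind(issues, new_issue(
      "fatal", "interval_mismatch", monitor_id, ok[i + 1L],
      sprintf("timestamp step of %g min is not a multiple of the %g-min acquisition interval",
              dt[i], step)))
  }
  if (any(issues$severity == "fatal")) {
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }

  gaps <- round(dt / step) - 1L  # missing readings between consecutive rows
  too_long <- which(gaps > max_gap)
  for (i in too_long) {
    issues <- rbind(issues, new_issue(
      "fatal", "timestamp_gap", monitor_id, ok[i + 1L],
      sprintf("%d consecutive readings missing (> %d); split the file or re-export",
              gaps[i], max_gap)))
  }
  if (any(issues$severity == "fatal")) {
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }

  records <- data.frame(reading_index = idx, timestamp = ts,
                        status_code = status, light_sensor = light)
  n_in <- nrow(records)

  # repair short gaps with zero-count records (reading_index 0 marks them)
  n_inserted <- 0L
  to_fill <- which(gaps >= 1L)
  if (length(to_fill) > 0L) {
    pieces_r <- list(); pieces_c <- list(); pieces_e <- list()
    prev <- 1L
    for (i in to_fill) {
      pieces_r[[length(pieces_r) + 1L]] <- records[prev:i, , drop = FALSE]
      pieces_c[[length(pieces_c) + 1L]] <- cnt[prev:i, , drop = FALSE]
      pieces_e[[length(pieces_e) + 1L]] <- extras[prev:i, , drop = FALSE]
      k <- gaps[i]
      fill_ts <- ts[i] + seq_len(k) * step * 60
      pieces_r[[length(pieces_r) + 1L]] <- data.frame(
        reading_index = 0L, timestamp = fill_ts,
        status_code = accepted_status[1L], light_sensor = light[i])
      pieces_c[[length(pieces_c) + 1L]] <- matrix(0, nrow = k,
                                                  ncol = DAM_N_CHANNELS)
      pieces_e[[length(pieces_e) + 1L]] <- matrix(0L, nrow = k, ncol = 5L)
      issues <- rbind(issues, new_issue(
        "warning", "timestamp_gap", monitor_id, ok[i + 1L],
        sprintf("gap of %d missing reading(s) before this row repaired with zero counts", k)))
      n_inserted <- n_inserted + k
      prev <- i + 1L
    }
    pieces_r[[length(pieces_r) + 1L]] <- records[prev:n_in, , drop = FALSE]
    pieces_c[[length(pieces_c) + 1L]] <- cnt[prev:n_in, , drop = FALSE]
    pieces_e[[length(pieces_e) + 1L]] <- extras[prev:n_in, , drop = FALSE]
    records <- do.call(rbind, pieces_r)
    cnt <- do.call(rbind, pieces_c)
    extras <- do.call(rbind, pieces_e)
    rownames(records) <- NULL
  }

  # drop hardware-error rows (status code outside the accepted set)
  bad_status <- which(!(records$status_code %in% accepted_status))
  n_dropped <- length(bad_status)
  if (n_dropped > 0L) {
    # map back to original row numbers where possible
    orig_row <- match(records$timestamp[bad_status], ts)
    for (j in seq_along(bad_status)) {
      issues <- rbind(issues, new_issue(
        "warning", "bad_status_code", monitor_id,
        if (is.na(orig_row[j])) NA else ok[orig_row[j]],
        sprintf("status code %d indicates a hardware error; reading dropped",
                records$status_code[bad_status[j]])))
    }
    records <- records[-bad_status, , drop = FALSE]
    cnt <- cnt[-bad_status, , drop = FALSE]
    extras <- extras[-bad_status, , drop = FALSE]
    rownames(records) <- NULL
  }
  if (nrow(records) == 0L) {
    issues <- rbind(issues, new_issue(
      "fatal", "bad_status_code", monitor_id, NA,
      "every row carries a hardware-error status code; no usable readings"))
    return(list(monitor = NULL, issues = issues, fatal = TRUE))
  }

  storage.mode(cnt) <- "integer"
  mon <- new_dam_monitor(monitor_id, interval_minutes, records, extras,
                         cnt, issues, n_rows_in = n_in,
                         n_dropped = n_dropped, n_inserted = n_inserted)
  list(monitor = mon, issues = issues, fatal = FALSE)
}

#' Read a DAMSystem3 monitor file
#'
#' Parses a tab-delimited TriKinetics monitor file (42 fields per row: reading
#' index, date, time, status code, five device fields, light sensor, and 32
#' per-channel beam-crossing counts), runs the hardware / data-integrity
#' checks, and returns a validated `dam_monitor` object.
#'
#' Validation rules: rows with a status code outside `accepted_status` are
#' dropped with a warning issue (hardware error); gaps of up to `max_gap`
#' missing readings are repaired by inserting zero-count records (warning);
#' longer gaps, wrong field counts, unparseable dates, negative counts,
#' duplicate or decreasing timestamps, and off-grid timestamp steps are fatal
#' and cause rejection with the full issue list attached to the error
#' condition (class `dam_io_error`).
#'
#' @param path Path to the monitor file.
#' @param interval_minutes Acquisition interval of the recording, in minutes.
#' @param accepted_status Integer status codes treated as valid readings.
#' @param max_gap Longest run of missing readings repaired with zero counts;
#'   longer gaps are fatal.
#' @param monitor_id Identifier for the monitor; defaults to the file name
#'   without extension.
#' @return A `dam_monitor`: list with `monitor_id`, `interval_minutes`,
#'   `records` (data frame: `reading_index`, `timestamp` (POSIXct, UTC),
#'   `status_code`, `light_sensor`), `counts` (integer matrix, one column per
#'   channel 1-32), `issues` (data frame of warnings), and the row-accounting
#'   fields `n_rows_in`, `n_dropped`, `n_inserted`.
#' @examples
#' tmp <- tempfile(fileext = ".txt")
#' specs <- lapply(1:32, function(i) fly_spec(paste0("f", i), baseline_rate = 1))
#' cal <- light_calendar(ld_start = "2017-01-01", ld_end = "2017-01-02")
#' gen <- generate_monitor(specs, cal, interval_minutes = 1, seed = 1,
#'                         monitor_id = "M1")
#' write_monitor_file(gen$monitor, tmp)
#' mon <- read_monitor_file(tmp, interval_minutes = 1)
#' count_channels(mon)
#' @seealso [write_monitor_file()], [validate_monitor_file()],
#'   [convert_channel_files()]
#' @export
read_monitor_file <- function(path, interval_minutes,
                              accepted_status = c(0L, 1L), max_gap = 6L,
                              monitor_id = NULL) {
  stopifnot(file.exists(path), interval_minutes > 0)
  if (is.null(monitor_id)) {
    monitor_id <- tools::file_path_sans_ext(basename(path))
  }
  res <- parse_monitor_lines(readLines(path, warn = FALSE), monitor_id,
                             interval_minutes, accepted_status, max_gap)
  if (res$fatal) dam_stop_issues(res$issues, monitor_id)
  res$monitor
}

#' Validate a monitor file without stopping on fatal issues
#'
#' Runs the same checks as [read_monitor_file()] but always returns the issue
#' table, making it suitable for pre-flight validation of a batch of files.
#'
#' @inheritParams read_monitor_file
#' @return Data frame of issues (possibly zero rows) with columns `severity`
#'   (`"warning"`/`"fatal"`), `kind`, `monitor_id`, `row`, `message`.
#' @export
validate_monitor_file <- function(path, interval_minutes,
                                  accepted_status = c(0L, 1L), max_gap = 6L,
                                  monitor_id = NULL) {
  stopifnot(file.exists(path), interval_minutes > 0)
  if (is.null(monitor_id)) {
    monitor_id <- tools::file_path_sans_ext(basename(path))
  }
  parse_monitor_lines(readLines(path, warn = FALSE), monitor_id,
                      interval_minutes, accepted_status, max_gap)$issues
}

#' Number of per-fly count channels in a monitor
#'
#' A DAM monitor records 32 channels, one fly per channel; this is a constant
#' of the monitor-file format and equals the number of count columns parsed.
#'
#' @param data A `dam_monitor` from [read_monitor_file()].
#' @return Integer, the number of channels (32 for any conforming file).
#' @export
count_channels <- function(data) {
  stopifnot(inherits(data, "dam_monitor"))
  ncol(data$counts)
}

#' Write a DAMSystem3 monitor file
#'
#' Serialises a `dam_monitor` back to the tab-delimited 42-field dialect read
#' by [read_monitor_file()]; `read_monitor_file(write_monitor_file(d))`
#' reproduces `d`'s records and counts exactly.
#'
#' @param data A `dam_monitor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_monitor_file <- function(data, path) {
  stopifnot(inherits(data, "dam_monitor"))
  if (nrow(data$records) == 0L) {
    stop("refusing to write a monitor file with no records", call. = FALSE)
  }
  ft <- dam_format_datetime(data$records$timestamp)
  extras <- data$extras
  if (is.null(extras)) extras <- matrix(0L, nrow(data$records), 5L)
  body <- cbind(data$records$reading_index, ft$date, ft$time,
                data$records$status_code, extras,
                data$records$light_sensor, data$counts)
  lines <- apply(body, 1L, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Convert legacy DAMSystem2 per-channel files into one monitor
#'
#' DAMSystem2 stores one tab-delimited file per fly with fields (reading
#' index, date, time, status, count) on a shared time grid. This merges up to
#' 32 such files column-wise into a `dam_monitor`; channels without a file are
#' filled with zero counts and flagged with a warning issue. Files that
#' disagree on the time grid are a fatal `interval_mismatch`.
#'
#' @param paths Character vector of 1-32 channel-file paths, in channel order.
#' @param monitor_id Identifier for the assembled monitor.
#' @param channels Channel numbers (1-32) the files map to; defaults to
#'   `seq_along(paths)`.
#' @return A `dam_monitor` serialisable with [write_monitor_file()].
#' @export
convert_channel_files <- function(paths, monitor_id,
                                  channels = seq_along(paths)) {
  stopifnot(length(paths) >= 1L, length(paths) <= DAM_N_CHANNELS,
            length(channels) == length(paths),
            all(channels %in% seq_len(DAM_N_CHANNELS)),
            !anyDuplicated(channels))
  issues <- empty_issues()
  ref <- NULL
  cnt <- matrix(0L, nrow = 0L, ncol = DAM_N_CHANNELS)
  for (k in seq_along(paths)) {
    lines <- sub("\r$", "", readLines(paths[k], warn = FALSE))
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 5L)) {
      issues <- rbind(issues, new_issue(
        "fatal", "wrong_column_count", monitor_id, which(lengths(f) < 5L)[1L],
        sprintf("channel file '%s' has rows with fewer than 5 fields", paths[k])))
      dam_stop_issues(issues, monitor_id)
    }
    m <- do.call(rbind, lapply(f, `[`, 1:5))
    ts <- dam_parse_datetime(m[, 2L], m[, 3L])
    if (anyNA(ts)) {
      issues <- rbind(issues, new_issue(
        "fatal", "malformed_row", monitor_id, which(is.na(ts))[1L],
        sprintf("channel file '%s' has unparseable date/time", paths[k])))
      dam_stop_issues(issues, monitor_id)
    }
    if (is.null(ref)) {
      ref <- list(ts = ts, idx = suppressWarnings(as.integer(m[, 1L])),
                  status = suppressWarnings(as.integer(m[, 4L])))
      cnt <- matrix(0L, nrow = length(ts), ncol = DAM_N_CHANNELS)
    } else if (length(ts) != length(ref$ts) || any(ts != ref$ts)) {
      issues <- rbind(issues, new_issue(
        "fatal", "interval_mismatch", monitor_id, NA,
        sprintf("channel file '%s' is not on the same time grid as '%s'",
                paths[k], paths[1L])))
      dam_stop_issues(issues, monitor_id)
    }
    cnt[, channels[k]] <- suppressWarnings(as.integer(m[, 5L]))
  }
  missing <- setdiff(seq_len(DAM_N_CHANNELS), channels)
  for (ch in missing) {
    issues <- rbind(issues, new_issue(
      "warning", "malformed_row", monitor_id, NA,
      sprintf("channel %d has no input file; filled with zero counts", ch)))
  }
  dt <- as.numeric(diff(ref$ts), units = "mins")
  if (length(unique(round(dt, 6))) > 1L) {
    issues <- rbind(issues, new_issue(
      "fatal", "interval_mismatch", monitor_id, NA,
      "channel files are not on a constant-interval time grid"))
    dam_stop_issues(issues, monitor_id)
  }
  records <- data.frame(reading_index = ref$idx, timestamp = ref$ts,
                        status_code = ref$status,
                        light_sensor = 0L)
  new_dam_monitor(monitor_id, if (length(dt)) dt[1L] else 1,
                  records, matrix(0L, nrow(records), 5L), cnt, issues,
                  n_rows_in = nrow(records))
}
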