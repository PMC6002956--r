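test_that("a well-formed file parses with no issues", {
  p <- write_fixture_monitor(withr::local_tempfile(fileext = ".txt"))
  mon <- read_monitor_file(p, 1)
  expect_s3_class(mon, "dam_monitor")
  expect_equal(nrow(mon$records), 3L)
  expect_equal(nrow(mon$issues), 0L)
  expect_equal(count_channels(mon), 32L)
  expect_equal(mon$records$timestamp[1],
               as.POSIXct("2017-01-01 00:00:00", tz = "UTC"))
})

test_that("a hardware-error status code drops the row with a warning issue", {
  p <- write_fixture_monitor(withr::local_tempfile(fileext = ".txt"),
                             n_rows = 3, status = c(1, 51, 1))
  mon <- read_monitor_file(p, 1)
  expect_equal(nrow(mon$records), 2L)
  expect_equal(nrow(mon$issues), 1L)
  expect_equal(mon$issues$kind, "bad_status_code")
  expect_equal(mon$issues$severity, "warning")
  expect_equal(mon$issues$row, 2L)
  # dropped-row accounting
  expect_equal(mon$n_rows_in, nrow(mon$records) + mon$n_dropped -
                 mon$n_inserted)
})

test_that("wrong field count, negative counts and bad dates are fatal", {
  p <- withr::local_tempfile(fileext = ".txt")
  lines <- c(monitor_line(1, "1 Jan 17", "00:00:00"),
             paste(rep("0", 41), collapse = "\t"))
  writeLines(lines, p)
  err <- tryCatch(read_monitor_file(p, 1), dam_io_error = identity)
  expect_s3_class(err, "dam_io_error")
  expect_equal(err$issues$kind, "wrong_column_count")

  cnt <- matrix(1, 2, 32); cnt[2, 5] <- -3
  p2 <- write_fixture_monitor(withr::local_tempfile(fileext = ".txt"),
                              n_rows = 2, counts = cnt)
  err2 <- tryCatch(read_monitor_file(p2, 1), dam_io_error = identity)
  expect_equal(err2$issues$kind, "negative_count")

  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(monitor_line(1, "1 Foo 17", "00:00:00"), p3)
  err3 <- tryCatch(read_monitor_file(p3, 1), dam_io_error = identity)
  expect_equal(err3$issues$kind, "malformed_row")
})

test_that("short gaps are repaired with zero counts, long gaps are fatal", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(monitor_line(1, "1 Jan 17", "00:00:00", counts = rep(2, 32)),
               monitor_line(2, "1 Jan 17", "00:02:00", counts = rep(2, 32))),
             p)
  mon <- read_monitor_file(p, 1)
  expect_equal(nrow(mon$records), 3L)
  expect_equal(mon$issues$kind, "timestamp_gap")
  expect_equal(mon$issues$severity, "warning")
  expect_true(all(mon$counts[2, ] == 0))
  expect_equal(mon$records$reading_index[2], 0L)  # marks insertion

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(monitor_line(1, "1 Jan 17", "00:00:00"),
               monitor_line(2, "1 Jan 17", "00:10:00")), p2)
  err <- tryCatch(read_monitor_file(p2, 1), dam_io_error = identity)
  expect_equal(err$issues$kind, "timestamp_gap")
  expect_equal(err$issues$severity, "fatal")
})

test_that("duplicate and off-grid timestamps are fatal", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(monitor_line(1, "1 Jan 17", "00:00:00"),
               monitor_line(2, "1 Jan 17", "00:00:00")), p)
  err <- tryCatch(read_monitor_file(p, 1), dam_io_error = identity)
  expect_equal(err$issues$kind, "duplicate_timestamp")

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(monitor_line(1, "1 Jan 17", "00:00:00"),
               monitor_line(2, "1 Jan 17", "00:02:00")), p2)
  err2 <- tryCatch(read_monitor_file(p2, 2), dam_io_error = NULL,
                   error = identity)
  # 2-min step at 2-min interval is fine; 3-min file at 2-min interval isn't
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(monitor_line(1, "1 Jan 17", "00:00:00"),
               monitor_line(2, "1 Jan 17", "00:03:00")), p3)
  err3 <- tryCatch(read_monitor_file(p3, 2), dam_io_error = identity)
  expect_equal(err3$issues$kind, "interval_mismatch")
})

test_that("CRLF line endings and two-digit years are handled", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeBin(charToRaw(paste0(monitor_line(1, "28 Feb 99", "12:30:05"), "\r\n",
                            monitor_line(2, "28 Feb 99", "12:31:05"), "\r\n")),
           p)
  mon <- read_monitor_file(p, 1)
  expect_equal(nrow(mon$records), 2L)
  expect_equal(as.Date(mon$records$timestamp[1]), as.Date("2099-02-28"))
})

test_that("write/read round-trip preserves records and counts", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  gen <- generate_monitor(list(fly_spec("a", baseline_rate = 2)), cal,
                          interval_minutes = 1, seed = 11, monitor_id = "M9")
  p <- withr::local_tempfile(fileext = ".txt")
  write_monitor_file(gen$monitor, p)
  back <- read_monitor_file(p, 1, monitor_id = "M9")
  expect_equal(back$records$reading_index, gen$monitor$records$reading_index)
  expect_true(all(back$records$timestamp == gen$monitor$records$timestamp))
  expect_equal(back$records$status_code, gen$monitor$records$status_code)
  expect_equal(unname(back$counts), unname(gen$monitor$counts))
  # a second write is byte-identical
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_monitor_file(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("writing an empty monitor is refused", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  gen <- generate_monitor(list(fly_spec("a")), cal, 1, 1)
  gen$monitor$records <- gen$monitor$records[0, ]
  expect_error(write_monitor_file(gen$monitor, tempfile()), "no records")
})

test_that("channel files merge into a monitor with zero-padded channels", {
  dirp <- withr::local_tempdir()
  ts <- sprintf("00:%02d:00", 0:4)
  for (ch in 1:2) {
    writeLines(vapply(1:5, function(i) {
      paste(c(i, "1 Jan 17", ts[i], 1, ch * 10 + i), collapse = "\t")
    }, character(1)), file.path(dirp, sprintf("ch%d.txt", ch)))
  }
  mon <- convert_channel_files(file.path(dirp, c("ch1.txt", "ch2.txt")), "MC")
  expect_equal(ncol(mon$counts), 32L)
  expect_equal(mon$counts[, 1], 10 + 1:5)
  expect_equal(mon$counts[, 2], 20 + 1:5)
  expect_true(all(mon$counts[, 3:32] == 0))
  expect_equal(sum(mon$issues$severity == "warning"), 30L)
  # and the result round-trips through the monitor-file dialect
  p <- withr::local_tempfile(fileext = ".txt")
  write_monitor_file(mon, p)
  back <- read_monitor_file(p, 1)
  expect_equal(unname(back$counts), unname(mon$counts))
})

test_that("channel files on different grids are a fatal interval mismatch", {
  dirp <- withr::local_tempdir()
  writeLines(paste(c(1, "1 Jan 17", "00:00:00", 1, 5), collapse = "\t"),
             file.path(dirp, "a.txt"))
  writeLines(paste(c(1, "1 Jan 17", "00:01:00", 1, 5), collapse = "\t"),
             file.path(dirp, "b.txt"))
  err <- tryCatch(
    convert_channel_files(file.path(dirp, c("a.txt", "b.txt")), "MC"),
    dam_io_error = identity)
  expect_equal(err$issues$kind[err$issues$severity == "fatal"],
               "interval_mismatch")
})
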