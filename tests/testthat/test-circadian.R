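test_that("an exact 24-h square wave peaks at 24.0 h and is rhythmic", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  x <- rep(rep(c(5, 0), each = 720), 6)
  pg <- chi_square_periodogram(fix_series(x, calendar = cal),
                               period_range = c(18, 30),
                               resolution_h = 0.5)
  expect_equal(pg$peak_period, 24)
  expect_true(pg$rhythmic)
  expect_gt(pg$rhythm_strength, 1)
  # scale invariance: Q is a ratio statistic
  pg10 <- chi_square_periodogram(fix_series(10 * x, calendar = cal),
                                 period_range = c(18, 30),
                                 resolution_h = 0.5)
  expect_equal(pg10$table$Q, pg$table$Q)
})

test_that("a constant series is flagged flat and arrhythmic", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  pg <- chi_square_periodogram(fix_series(rep(3, 6 * 1440), calendar = cal))
  expect_false(pg$rhythmic)
  expect_equal(pg$rhythm_strength, 0)
  expect_true(is.na(pg$peak_period))
})

test_that("a pure sinusoid is recovered within one resolution step", {
  cal <- fix_calendar(ld_days = 0, dd_days = 7)
  for (tau in c(21.5, 24, 26.5)) {
    h <- (0:(7 * 1440 - 1)) / 60
    x <- 2 + 2 * sin(2 * pi * h / tau)
    pg <- chi_square_periodogram(fix_series(x, calendar = cal),
                                 period_range = c(18, 30),
                                 resolution_h = 0.5)
    expect_lte(abs(pg$peak_period - tau), 0.5)
  }
})

test_that("Q matches the brute-force fold to 1e-9 relative error", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  set.seed(43)
  for (rep in 1:10) {
    x <- rpois(6 * 1440, runif(1, 0.2, 2))
    pg <- chi_square_periodogram(fix_series(x, calendar = cal),
                                 period_range = c(18, 30),
                                 resolution_h = 0.5)
    xb <- colSums(matrix(x, nrow = pg$bin_minutes))
    qo <- csp_oracle(xb, pg$table$p_bins)
    expect_lt(max(abs(pg$table$Q - qo) / pmax(abs(qo), 1e-12)), 1e-9)
  }
})

test_that("the significance line uses p-1 degrees of freedom", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  pg <- chi_square_periodogram(fix_series(rpois(6 * 1440, 1),
                                          calendar = cal),
                               period_range = c(18, 30), resolution_h = 0.5,
                               alpha = 0.05, correction = "none")
  expect_equal(pg$table$S,
               qchisq(0.95, df = pg$table$p_bins - 1))
})

test_that("unrepresentable resolutions and short series are errors", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  s <- fix_series(rpois(6 * 1440, 1), calendar = cal)
  expect_error(chi_square_periodogram(s, resolution_h = 1 / 70),
               "resolution")
  short <- fix_series(rpois(1440, 1), calendar = fix_calendar(0, 1))
  expect_error(chi_square_periodogram(short), "cycles")
})

test_that("the periodogram restricts to DD days via the calendar", {
  cal <- fix_calendar(ld_days = 3, dd_days = 6)
  # entrained 24-h wave in LD, free-running 26-h wave in DD
  h_ld <- (0:(3 * 1440 - 1)) / 60
  h_dd <- (0:(6 * 1440 - 1)) / 60
  x <- c(2 + 2 * sin(2 * pi * h_ld / 24), 2 + 2 * sin(2 * pi * h_dd / 26))
  s <- fix_series(x, calendar = cal)
  pg <- chi_square_periodogram(s, period_range = c(18, 30),
                               resolution_h = 0.5, calendar = cal)
  expect_equal(pg$peak_period, 26)
  # LD analysis works only under protest (and the short LD span still
  # needs a representable range)
  expect_warning(
    chi_square_periodogram(s, period_range = c(18, 24), resolution_h = 0.5,
                           calendar = cal, use_regime = "LD"),
    "LD")
})

test_that("filter_arrhythmic partitions inclusively at the threshold", {
  mk <- function(s) structure(list(rhythm_strength = s),
                              class = "periodogram")
  res <- lapply(c(0.4, 1.0, 2.3), mk)
  part <- filter_arrhythmic(res, 1)
  expect_length(part$rhythmic, 2L)
  expect_length(part$arrhythmic, 1L)
  expect_length(filter_arrhythmic(res, 0)$rhythmic, 3L)
})

test_that("aggregate_periodogram averages pointwise across flies", {
  cal <- fix_calendar(ld_days = 0, dd_days = 6)
  x <- rep(rep(c(5, 0), each = 720), 6)
  pg <- chi_square_periodogram(fix_series(x, calendar = cal),
                               period_range = c(20, 28),
                               resolution_h = 0.5)
  one <- aggregate_periodogram(list(pg))
  expect_equal(one$mean_Q, pg$table$Q)
  two <- aggregate_periodogram(list(pg, pg))
  expect_equal(two$mean_Q, pg$table$Q)
  expect_true(all(two$sem_Q == 0))
  pg2 <- chi_square_periodogram(fix_series(x, calendar = cal),
                                period_range = c(18, 30),
                                resolution_h = 0.5)
  expect_error(aggregate_periodogram(list(pg, pg2)), "grids")
})

test_that("actogram matrices have the documented shape and redundancy", {
  cal <- fix_calendar(ld_days = 2, dd_days = 0)
  set.seed(47)
  s <- fix_series(rpois(2 * 1440, 1), calendar = cal)
  single <- build_actogram(s, cal, bin_minutes = 30, style = "single")
  expect_equal(dim(single$matrix), c(2L, 48L))
  dbl <- build_actogram(s, cal, bin_minutes = 30, style = "double")
  expect_equal(dim(dbl$matrix), c(2L, 96L))
  # right half of row d = left half of row d+1; last right half is NA
  expect_equal(dbl$matrix[1, 49:96], dbl$matrix[2, 1:48],
               ignore_attr = TRUE)
  expect_true(all(is.na(dbl$matrix[2, 49:96])))
  expect_equal(unname(dbl$matrix[, 1:48]), unname(single$matrix))
})

test_that("aggregate actograms take the median or mean across flies", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  vals <- c(0, 5, 100)
  ser <- lapply(seq_along(vals), function(i) {
    fix_series(rep(vals[i] / 60, 1440), calendar = cal,
               fly_id = paste0("f", i))
  })
  med <- build_actogram(ser, cal, bin_minutes = 60, stat = "median")
  expect_true(all(med$matrix == 5))
  avg <- build_actogram(ser, cal, bin_minutes = 60, stat = "mean")
  expect_true(all(abs(avg$matrix - 35) < 1e-9))
})
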