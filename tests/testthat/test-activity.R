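test_that("condition summaries are fly-mean based with SEM across flies", {
  cal <- fix_calendar(ld_days = 2, dd_days = 0)
  s1 <- fix_series(rep(100 / 1440, 2 * 1440), calendar = cal,
                   fly_id = "f1")
  s2 <- fix_series(rep(200 / 1440, 2 * 1440), calendar = cal,
                   fly_id = "f2")
  fd <- fly_day_table(list(f1 = s1, f2 = s2), cal)
  out <- condition_daily_activity(fd, "LD")
  expect_equal(out$summary$mean, 150)
  expect_equal(out$summary$sem, 50)
  expect_equal(out$summary$n, 2L)
  # single fly: SEM is NA, not an error
  out1 <- condition_daily_activity(fly_day_table(list(f1 = s1), cal), "LD")
  expect_true(is.na(out1$summary$sem))
})

test_that("day + night totals equal the whole-day total in LD", {
  cal <- fix_calendar(ld_days = 3, dd_days = 0)
  set.seed(9)
  ser <- lapply(1:4, function(i) {
    fix_series(rpois(3 * 1440, 0.7), calendar = cal,
               fly_id = paste0("f", i))
  })
  names(ser) <- paste0("f", 1:4)
  fd <- fly_day_table(ser, cal)
  ld <- fd[fd$regime == "LD" & fd$complete, ]
  expect_equal(ld$day_total + ld$night_total, ld$total)
})

test_that("a doubled rate on one day shows up in the by-day means", {
  cal <- fix_calendar(ld_days = 0, dd_days = 5)
  set.seed(31)
  rate <- rep(1, 5 * 1440)
  rate[(2 * 1440 + 1):(3 * 1440)] <- 2  # day 3 doubled
  ser <- lapply(1:16, function(i) {
    fix_series(rpois(length(rate), rate), calendar = cal,
               fly_id = paste0("f", i))
  })
  names(ser) <- paste0("f", 1:16)
  byday <- activity_by_day(fly_day_table(ser, cal))
  m <- byday$mean
  expect_equal(length(m), 5L)
  expect_gt(m[3] / mean(m[-3]), 1.8)
  expect_lt(m[3] / mean(m[-3]), 2.2)
})

test_that("mean of simulated flies matches the programmed rate", {
  cal <- fix_calendar(ld_days = 0, dd_days = 3)
  gen <- generate_monitor(lapply(1:32, function(i) {
    fly_spec(paste0("f", i), baseline_rate = 0.5)
  }), cal, 1, seed = 13)
  layout <- experiment_layout(list(condition("c", "M1", 1:32)), cal, 1, 0)
  ser <- extract_fly_series(list(M1 = gen$monitor), layout)
  out <- condition_daily_activity(fly_day_table(ser, cal), "DD")
  programmed <- 0.5 * 1440
  expect_lt(abs(out$summary$mean - programmed), 3 * out$summary$sem + 1e-9)
})

test_that("ld_average profile of a square-wave day has silent nights", {
  cal <- fix_calendar(ld_days = 3, dd_days = 0)
  day_pattern <- rep(c(2, 0), each = 720)  # active in day phase only
  ser <- list(f1 = fix_series(rep(day_pattern, 3), calendar = cal,
                              fly_id = "f1", condition = "c"))
  prof <- activity_profile(ser, cal, bin_minutes = 60, mode = "ld_average")
  expect_equal(nrow(prof), 24L)
  expect_true(all(prof$mean[prof$bin_start < 12] > 0))
  expect_true(all(prof$mean[prof$bin_start >= 12] == 0))
  # averaging identical days is idempotent: equals one day's profile
  one <- activity_profile(
    list(f1 = fix_series(day_pattern, calendar = cal, fly_id = "f1")),
    fix_calendar(ld_days = 1, dd_days = 0), 60, "ld_average")
  expect_equal(prof$mean, one$mean)
})

test_that("full-experiment profile at native bin equals the raw means", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  s1 <- fix_series(c(1, 2, 3, 4), calendar = cal, fly_id = "a")
  s2 <- fix_series(c(3, 2, 1, 0), calendar = cal, fly_id = "b")
  prof <- activity_profile(list(a = s1, b = s2), cal, bin_minutes = 1,
                           mode = "full_experiment")
  expect_equal(prof$mean, c(2, 2, 2, 2))
  expect_equal(prof$n, rep(2L, 4))
})

test_that("activity bouts are maximal positive runs assigned to onset day", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  s <- fix_series(c(0, 2, 3, 0, 0, 1, 0), calendar = cal)
  b <- activity_bouts(s, cal)
  expect_equal(b$bout_count, 2L)
  expect_equal(b$mean_bout_length_min, 1.5)
  # all-zero day: zero bouts, flagged
  z <- activity_bouts(fix_series(rep(0, 10), calendar = cal), cal)
  expect_equal(z$bout_count, 0L)
  expect_equal(z$mean_bout_length_min, 0)
  expect_false(z$has_bouts)
})

test_that("bout statistics agree with a brute-force run scan", {
  cal <- fix_calendar(ld_days = 0, dd_days = 2)
  set.seed(17)
  for (rep in 1:20) {
    x <- rpois(2 * 1440, 0.5)
    s <- fix_series(x, calendar = cal)
    b <- activity_bouts(s, cal)
    lens <- bout_oracle(x > 0)
    expect_equal(sum(b$bout_count), length(lens))
    expect_equal(sum(b$total_bout_min), sum(lens))
    # bout decomposition: total bout minutes = active readings x interval
    expect_equal(sum(b$total_bout_min), sum(x > 0))
  }
})
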