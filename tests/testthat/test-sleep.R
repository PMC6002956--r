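test_that("five consecutive zero minutes are sleep, four are not", {
  st <- detect_sleep(count_series(c(3, 0, 0, 0, 0, 0, 2)))
  expect_equal(st$sleep, c(0L, 1L, 1L, 1L, 1L, 1L, 0L))
  st4 <- detect_sleep(count_series(c(3, 0, 0, 0, 0, 2)))
  expect_equal(sum(st4$sleep), 0L)
})

test_that("boundary-touching inactivity runs count at observed length", {
  st <- detect_sleep(count_series(c(0, 0, 0, 0, 0, 1)))
  expect_equal(st$sleep, c(1L, 1L, 1L, 1L, 1L, 0L))
  st2 <- detect_sleep(count_series(c(1, 0, 0, 0, 0)))  # only 4 observed
  expect_equal(sum(st2$sleep), 0L)
})

test_that("coarse intervals are scored at native resolution or rejected", {
  s5 <- count_series(c(4, 0, 3), interval_minutes = 5)
  st <- detect_sleep(s5)  # one 5-min zero reading = one sleep window
  expect_equal(length(st$sleep), 15L)
  expect_equal(sum(st$sleep), 5L)
  s10 <- count_series(c(1, 0), interval_minutes = 10)
  expect_error(detect_sleep(s10), "too coarse")
  s2 <- count_series(c(1, 0, 0), interval_minutes = 2)
  expect_error(detect_sleep(s2), "not a multiple")
})

test_that("sliding-window and maximal-run formulations agree", {
  set.seed(23)
  for (rep in 1:200) {
    x <- rbinom(sample(20:200, 1), 1, runif(1, 0.1, 0.9))
    st <- detect_sleep(count_series(x))
    expect_identical(st$sleep, sleep_oracle_sliding(x, 5))
  }
})

test_that("sleep set shrinks as the window grows", {
  set.seed(29)
  for (rep in 1:20) {
    x <- rbinom(300, 1, 0.3)
    prev <- detect_sleep(count_series(x), window_minutes = 3)$sleep
    for (w in c(5, 10, 15)) {
      cur <- detect_sleep(count_series(x), window_minutes = w)$sleep
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("no sleep bout is shorter than the window", {
  set.seed(37)
  for (rep in 1:30) {
    x <- rbinom(500, 1, 0.4)
    st <- detect_sleep(count_series(x))
    lens <- bout_oracle(st$sleep == 1L)
    if (length(lens)) expect_true(all(lens >= 5))
  }
})

test_that("sleep summaries split phases and conserve the day", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  asleep <- fix_series(rep(0, 1440), calendar = cal)
  ss <- sleep_summary(detect_sleep(asleep), cal)
  expect_equal(ss$sleep_total_min, 1440)
  expect_equal(ss$sleep_day_min, 720)
  expect_equal(ss$sleep_night_min, 720)
  # never-sleeping fixture: no zero run reaches 5 min
  awake <- fix_series(rep(c(1, 0, 0, 0, 0), 288), calendar = cal)
  sa <- sleep_summary(detect_sleep(awake), cal)
  expect_equal(sa$sleep_total_min, 0)
  # one programmed 120-min night rest
  x <- rep(1, 1440)
  x[721:840] <- 0  # minutes 720-839 after onset = night phase
  sr <- sleep_summary(detect_sleep(fix_series(x, calendar = cal)), cal)
  expect_equal(sr$sleep_night_min, 120)
  expect_equal(sr$sleep_day_min, 0)
  # sleep + wake = span
  expect_equal(sr$sleep_total_min + (1440 - 120), 1440)
})

test_that("sleep profile averages fractions across flies", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  all_sleep <- detect_sleep(fix_series(rep(0, 1440), calendar = cal,
                                       fly_id = "s", condition = "c"))
  no_sleep <- detect_sleep(fix_series(rep(1, 1440), calendar = cal,
                                      fly_id = "w", condition = "c"))
  p1 <- sleep_profile(list(all_sleep), cal, 60)
  expect_true(all(p1$mean == 1))
  p2 <- sleep_profile(list(all_sleep, no_sleep), cal, 60)
  expect_true(all(p2$mean == 0.5))
  # alternating 15-min sleep/wake in 30-min bins -> exactly one half
  alt <- detect_sleep(fix_series(rep(rep(c(0, 1), each = 15), 48),
                                 calendar = cal, fly_id = "a",
                                 condition = "c"))
  p3 <- sleep_profile(list(alt), cal, 30)
  expect_true(all(p3$mean == 0.5))
})

test_that("sleep bouts report count and mean length per day", {
  cal <- fix_calendar(ld_days = 1, dd_days = 0)
  x <- rep(1, 1440)
  x[101:400] <- 0  # one 300-min rest
  sb <- sleep_bouts(detect_sleep(fix_series(x, calendar = cal)), cal)
  expect_equal(sb$bout_count, 1L)
  expect_equal(sb$mean_bout_length_min, 300)
  x2 <- rep(1, 1440)
  x2[11:15] <- 0   # 5-min bout
  x2[31:36] <- 0   # 6-min bout
  sb2 <- sleep_bouts(detect_sleep(fix_series(x2, calendar = cal)), cal)
  expect_equal(sb2$bout_count, 2L)
  expect_equal(sb2$mean_bout_length_min, 5.5)
})
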