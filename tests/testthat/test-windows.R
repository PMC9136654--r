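test_that("margins merge consecutive visits into one window", {
  v <- tibble::tibble(
    physician_id = "p1",
    start = ts(c("2019-09-03 09:00:00", "2019-09-03 09:20:00")),
    end = ts(c("2019-09-03 09:20:00", "2019-09-03 09:40:00"))
  )
  w <- build_clinic_windows(v, margin_min = 30)
  expect_equal(nrow(w), 1L)
  expect_equal(w$window_start, ts("2019-09-03 08:30:00"))
  expect_equal(w$window_end, ts("2019-09-03 10:10:00"))
})

test_that("well-separated visits give separate windows", {
  v <- tibble::tibble(
    physician_id = "p1",
    start = ts(c("2019-09-03 09:00:00", "2019-09-03 14:00:00")),
    end = ts(c("2019-09-03 09:20:00", "2019-09-03 14:20:00"))
  )
  w <- build_clinic_windows(v, margin_min = 30)
  expect_equal(nrow(w), 2L)
  expect_equal(w$window_start,
               ts(c("2019-09-03 08:30:00", "2019-09-03 13:30:00")))
  expect_equal(w$window_end,
               ts(c("2019-09-03 09:50:00", "2019-09-03 14:50:00")))
  # every generating visit is inside a window with full margin slack
  expect_true(all(w$window_start + 30 * 60 <= v$start &
                    v$end + 30 * 60 <= w$window_end))
})

test_that("no visits means no windows and all time outside", {
  w <- build_clinic_windows(tibble::tibble(
    physician_id = character(0),
    start = ts(character(0)), end = ts(character(0))))
  expect_equal(nrow(w), 0L)
  acts <- events_at(0)
  acts$duration_s <- 300
  seg <- segment_actions(acts, w)
  expect_equal(seg$during_s, 0)
  expect_equal(seg$outside_s, 300)
  expect_equal(seg$segment, "outside")
})

test_that("boundary-straddling actions split by clock time", {
  w <- windows_at(8.5 * 3600, 10 * 3600 + 600) # 08:30-10:10
  # fully inside
  a <- events_at(3600) # 09:00
  a$duration_s <- 60
  s <- segment_actions(a, w)
  expect_equal(s$during_s, 60)
  expect_equal(s$outside_s, 0)
  # starts 10:09, runs 120 s across the 10:10 boundary
  b <- events_at(2 * 3600 + 9 * 60) # base 08:00 + 2:09 = 10:09
  b$duration_s <- 120
  s <- segment_actions(b, w)
  expect_equal(s$during_s, 60)
  expect_equal(s$outside_s, 60)
  expect_equal(s$segment, "during") # primary label follows the start
})

test_that("half-open convention: event at a window's end is outside", {
  w <- windows_at(3600, 7200)
  a <- events_at(c(3600, 7200), base = "2019-09-03 00:00:00")
  a$duration_s <- c(0, 0)
  s <- segment_actions(a, w)
  expect_equal(s$segment, c("during", "outside"))
})

test_that("straddle policy 'start' assigns whole durations by start", {
  w <- windows_at(8.5 * 3600, 10 * 3600 + 600)
  b <- events_at(2 * 3600 + 9 * 60)
  b$duration_s <- 120
  s <- segment_actions(b, w, straddle = "start")
  expect_equal(s$during_s, 120)
  expect_equal(s$outside_s, 0)
})

test_that("decomposition conserves duration and matches the oracle", {
  withr::local_seed(23)
  for (rep in 1:60) {
    wins <- random_windows(sample(0:4, 1), 5000)
    w <- windows_at(wins$starts, wins$ends)
    n <- 12
    t0 <- sample.int(6000, n)
    dur <- sample(0:600, n, replace = TRUE)
    a <- events_at(t0, base = "2019-09-03 00:00:00")
    a$duration_s <- dur
    s <- segment_actions(a, w)
    expect_equal(s$during_s + s$outside_s, as.numeric(dur))
    base_n <- as.numeric(ts("2019-09-03 00:00:00"))
    expected <- mapply(oracle_during_seconds, base_n + t0, dur,
                       MoreArgs = list(win_starts = base_n + wins$starts,
                                       win_ends = base_n + wins$ends))
    expect_equal(s$during_s, as.numeric(expected))
  }
})

test_that("enlarging the margin never decreases total during-time", {
  withr::local_seed(31)
  v <- tibble::tibble(
    physician_id = "u1",
    start = ts("2019-09-03 00:00:00") + sort(sample.int(20000, 5)),
    end = NA
  )
  v$end <- v$start + sample(300:1200, 5, replace = TRUE)
  a <- events_at(sample.int(30000, 200), base = "2019-09-03 00:00:00")
  a <- a[order(a$timestamp), ]
  a$duration_s <- sample(0:900, 200, replace = TRUE)
  totals <- vapply(c(0, 5, 30, 60, 180), function(m) {
    sum(segment_actions(a, build_clinic_windows(v, m))$during_s)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})
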