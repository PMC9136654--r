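test_that("access time is the gap to the same user's next event", {
  ev <- events_at(c(0, 100, 200))
  expect_equal(estimate_access_time(ev)$duration_s, c(100, 100, 0))
  # single event: no successor
  expect_equal(estimate_access_time(events_at(0))$duration_s, 0)
})

test_that("deltas never cross users and conserve each user's span", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    ev <- dplyr::bind_rows(
      events_at(sort(sample.int(10000, n1)), user = "a"),
      events_at(sort(sample.int(10000, n2)), user = "b")
    )
    timed <- estimate_access_time(ev)
    spans <- tapply(as.numeric(ev$timestamp), ev$user_id,
                    function(t) max(t) - min(t))
    sums <- tapply(timed$duration_s, timed$user_id, sum)
    expect_equal(as.numeric(sums), as.numeric(spans))
  }
})

test_that("unsorted input is rejected", {
  ev <- events_at(c(100, 0))
  expect_error(estimate_access_time(ev), "sorted")
  ev2 <- dplyr::bind_rows(events_at(0, user = "b"),
                          events_at(0, user = "a"))
  expect_error(estimate_access_time(ev2), "sorted")
})

test_that("idle removal is strict: exactly-at-cutoff is retained", {
  acts <- events_at(c(0, 1, 2))
  acts$duration_s <- c(14, 15, 16) * 60
  out <- filter_idle(acts, cutoff_min = 15)
  expect_equal(out$duration_s, c(14, 15) * 60)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(attr(out, "removed_seconds"), 16 * 60)
})

test_that("idle filter limits: empty input, infinite cutoff, idempotence", {
  empty <- events_at(numeric(0))
  empty$duration_s <- numeric(0)
  expect_equal(nrow(filter_idle(empty)), 0L)

  acts <- events_at(1:5)
  acts$duration_s <- c(10, 2000, 30, 5000, 1)
  expect_equal(filter_idle(acts, cutoff_min = Inf)$duration_s,
               acts$duration_s)
  once <- filter_idle(acts, 15)
  twice <- filter_idle(once, 15)
  expect_equal(twice, once, ignore_attr = TRUE)
  expect_equal(attr(twice, "n_removed"), 0L)
})

test_that("retained time is monotone non-decreasing in the cutoff", {
  withr::local_seed(5)
  acts <- events_at(seq_len(200))
  acts$duration_s <- rlnorm(200, log(60), 2)
  totals <- vapply(c(1, 5, 15, 60, 240), function(cut) {
    sum(filter_idle(acts, cut)$duration_s)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("zero_duration policy keeps events for counting", {
  acts <- events_at(1:3)
  acts$duration_s <- c(10, 2000, 30)
  out <- filter_idle(acts, 15, policy = "zero_duration")
  expect_equal(nrow(out), 3L)
  expect_equal(out$duration_s, c(10, 0, 30))
  expect_equal(attr(out, "removed_seconds"), 2000)
})
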