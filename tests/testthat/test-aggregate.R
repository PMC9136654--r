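test_that("cohort exclusions follow status, cFTE, and visit rules", {
  roster <- make_roster(sprintf("p%02d", 1:62))
  roster$employment_status[1:4] <- "contingent"
  roster$cfte[5] <- 0
  visits <- tibble::tibble(physician_id = roster$physician_id[-6],
                           start = ts("2019-09-03 09:00:00"),
                           end = ts("2019-09-03 09:20:00"))
  out <- filter_cohort(roster, visits)
  expect_equal(sum(out$eligible), 56L)
  tally <- attr(out, "exclusions")
  expect_equal(tally$contingent, 4L)
  expect_equal(tally$zero_cfte, 1L)
  expect_equal(tally$no_visits, 1L)
  expect_equal(length(eligible_ids(out)), 56L)
})

test_that("cohort filter identity and all-excluded limits", {
  roster <- make_roster(c("a", "b"))
  visits <- tibble::tibble(physician_id = c("a", "b"),
                           start = ts("2019-09-03 09:00:00"),
                           end = ts("2019-09-03 09:20:00"))
  expect_true(all(filter_cohort(roster, visits)$eligible))
  disjoint <- tibble::tibble(physician_id = "zz",
                             start = ts("2019-09-03 09:00:00"),
                             end = ts("2019-09-03 09:20:00"))
  out <- filter_cohort(roster, disjoint)
  expect_false(any(out$eligible))
  expect_equal(unique(out$exclusion_reason), "no_visits")
})

test_that("daily summary converts seconds and honours workday rules", {
  acts <- make_segmented(tibble::tibble(during_s = 60, segment = "during"))
  daily <- summarize_daily(acts)
  expect_equal(daily$hours_during, 1 / 60)
  expect_equal(daily$n_during, 1L)
  expect_true(daily$workday)

  # a day with visits but no events yields a zero-hours row
  visits <- tibble::tibble(physician_id = "p2",
                           start = ts("2019-09-04 09:00:00"),
                           end = ts("2019-09-04 09:20:00"))
  daily2 <- summarize_daily(acts, visits)
  expect_equal(nrow(daily2), 2L)
  row2 <- daily2[daily2$physician_id == "p2", ]
  expect_equal(row2$hours_during + row2$hours_outside, 0)
  expect_true(row2$workday) # rule "either"
  daily3 <- summarize_daily(acts, visits, workday = "events")
  expect_false(daily3$workday[daily3$physician_id == "p2"])
  daily4 <- summarize_daily(acts, visits, workday = "visits")
  expect_false(daily4$workday[daily4$physician_id == "p1"])
})

test_that("per-category daily hours sum to the daily totals", {
  sim <- quiet_sim(small_config())
  res <- run_pipeline(sim$access_log, sim$visits, sim$roster,
                      sim$action_map)
  by_cat <- summarize_daily_categories(res$actions) |>
    dplyr::group_by(physician_id, date) |>
    dplyr::summarise(hours_during = sum(hours_during),
                     hours_outside = sum(hours_outside), .groups = "drop")
  joined <- dplyr::inner_join(
    by_cat, res$daily, by = c("physician_id", "date"),
    suffix = c("_cat", "_tot"))
  expect_equal(joined$hours_during_cat, joined$hours_during_tot,
               tolerance = 1e-9)
  expect_equal(joined$hours_outside_cat, joined$hours_outside_tot,
               tolerance = 1e-9)
})

test_that("category table reproduces the printed worked example", {
  ct <- category_table(table2_actions(), n_workdays = 1)
  tot <- ct[ct$clinical_category == "total", ]
  expect_equal(tot$hours_outside, 0.76)
  expect_equal(tot$hours_total, 5.12)
  expect_equal(tot$hours_during, 4.36) # unrounded column sum
  # percent columns sum to 100 within integer rounding
  cats <- ct[ct$clinical_category != "total", ]
  expect_lte(abs(sum(cats$pct_during) - 100), 1)
  expect_lte(abs(sum(cats$pct_outside) - 100), 1)
  expect_lte(abs(sum(cats$pct_total) - 100), 1)
  expect_equal(cats$hours_during[cats$clinical_category == "review"], 3.13)
  expect_equal(cats$pct_outside[cats$clinical_category == "review"], 78)
})

test_that("top-action table reproduces the printed totals", {
  ta <- top_actions(table3_actions(), n_workdays = 1, k = 3)
  tot <- ta[ta$clinical_category == "total", ]
  expect_equal(tot$freq, 74)
  expect_equal(tot$minutes, 25.4)
  expect_equal(nrow(ta), 13L)
  first_review <- ta[ta$clinical_category == "review", ][1, ]
  expect_equal(first_review$action_code, "patient_data_viewed")
  expect_equal(first_review$freq, 28)
  expect_equal(first_review$minutes, 12.7)
  # frequency tie within review (4 vs 4) broken by larger minutes
  expect_equal(ta$action_code[2:3],
               c("encounter_data_viewed", "clinical_notes_viewed"))
})

test_that("single dominant action tops its category", {
  acts <- make_segmented(tibble::tibble(
    clinical_category = "inbox", action_code = "only_one",
    outside_s = 120, segment = "outside"))
  ta <- top_actions(acts, n_workdays = 1)
  expect_equal(ta$action_code[1], "only_one")
  expect_equal(ta$minutes[nrow(ta)], ta$minutes[1])
})

test_that("administrative time is the stated share of nominal hours", {
  expect_equal(admin_time(100, 0.11, 22), 0.5)
  expect_equal(admin_time(100, 0, 22), 0)
  expect_error(admin_time(100, 0.11, 0), "positive")
})

test_that("high-user selection is strictly greater-than", {
  daily <- tibble::tibble(
    physician_id = rep(c("a", "b", "c"), each = 2),
    date = rep(as.Date("2019-09-03") + 0:1, 3),
    has_events = TRUE, has_visits = TRUE, workday = TRUE,
    hours_during = 4,
    hours_outside = rep(c(0.4, 1.5, 1.6), each = 2),
    n_during = 1L, n_outside = 1L
  )
  hu <- high_users(daily, threshold_hours = 1.5)
  expect_equal(hu$physician_means$physician_id, "c")
  expect_equal(hu$n_physicians, 1L)
  expect_equal(hu$hours$mean[hu$hours$segment == "outside"], 1.6)
  # all below threshold: empty subgroup, no error
  expect_message(out <- high_users(daily, threshold_hours = 5),
                 "no physician")
  expect_null(out)
})

test_that("cohort summary averages per physician then across physicians", {
  daily <- tibble::tibble(
    physician_id = c("a", "a", "b"),
    date = as.Date("2019-09-03") + c(0, 1, 0),
    has_events = TRUE, has_visits = TRUE, workday = TRUE,
    hours_during = c(2, 4, 6), hours_outside = c(0, 1, 2),
    n_during = 1L, n_outside = 0L
  )
  cs <- summarize_cohort(daily)
  expect_equal(cs$n_physicians, 2L)
  expect_equal(cs$n_workdays, 3L)
  h <- cs$hours
  expect_equal(h$mean[h$segment == "during"], mean(c(3, 6)))
  expect_equal(h$mean[h$segment == "outside"], mean(c(0.5, 2)))
  # pooled divides total hours by total workdays
  expect_equal(cs$pooled$hours_per_workday[cs$pooled$segment == "during"],
               12 / 3)
  g <- glance(cs)
  expect_equal(g$mean_during, 4.5)
  expect_s3_class(tidy(cs), "tbl_df")
})
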