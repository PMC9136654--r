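test_that("R2 partition arithmetic is forced by its definition", {
  r2 <- r2_components(1, 4, 5)
  expect_equal(unname(r2), c(10, 40, 50))
  expect_equal(unname(r2_components(0, 4, 6))[1], 0) # null fixed part
  expect_error(r2_components(0, 0, 0), "zero")
})

test_that("constant outcomes give a degenerate zero-variance fit", {
  md <- simulate_model_data(n_providers = 8, n_days = 5, seed = 3)
  md$daily$hours_outside <- 2.5
  fit <- fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("outside"))
  expect_true(fit$degenerate)
  expect_equal(fit$coefficients$estimate[1], 2.5)
  expect_true(all(fit$coefficients$estimate[-1] == 0))
  expect_true(all(fit$varcomp$variance == 0))
  expect_error(r2_partition(fit), "zero")
})

test_that("with no random terms the fit reduces to OLS", {
  md <- simulate_model_data(n_providers = 12, n_days = 8, seed = 5)
  fit <- fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("outside"),
                       random = character(0))
  mf <- md$daily |>
    dplyr::left_join(md$roster, by = "physician_id") |>
    dplyr::mutate(gender_female = as.numeric(sex == "female"),
                  during_minutes = hours_during * 60)
  ref <- lm(hours_outside ~ during_minutes + age + gender_female + cfte,
            data = mf)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("zero-noise data are recovered exactly", {
  beta <- c("(Intercept)" = 1.5, during_minutes = -0.003, age = -0.01,
            gender_female = -0.5, cfte = 0.8)
  md <- simulate_model_data(n_providers = 20, n_days = 10, beta = beta,
                            sd_provider = 0, sd_day = 0, sd_resid = 0,
                            seed = 9)
  fit <- suppressWarnings( # lm warns on an essentially perfect fit
    fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("outside"),
                  random = character(0)))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[names(beta)], beta, tolerance = 1e-8)
})

test_that("zero generated random variance yields near-zero random R2", {
  md <- simulate_model_data(n_providers = 30, n_days = 15,
                            sd_provider = 0, sd_day = 0, sd_resid = 0.5,
                            seed = 13)
  fit <- suppressMessages(
    fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("outside")))
  r2 <- r2_partition(fit)
  expect_lt(r2[["r2_random"]], 5)
  expect_true(fit$singular)
})

test_that("R2 partition is additive and affine-invariant", {
  md <- simulate_model_data(n_providers = 25, n_days = 12, seed = 17)
  fit <- fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("outside"))
  r2 <- r2_partition(fit)
  expect_equal(r2[["r2_fixed"]] + r2[["r2_random"]], r2[["r2_total"]],
               tolerance = 0.1)
  rescaled <- md$daily
  rescaled$hours_outside <- 3.7 * rescaled$hours_outside + 11
  fit2 <- fit_ehr_mixed(rescaled, md$roster, ehr_model_spec("outside"))
  expect_equal(unname(r2_partition(fit2)), unname(r2), tolerance = 0.02)
})

test_that("weekly aggregation sums ISO weeks and fits the crossed model", {
  daily <- tibble::tibble(
    physician_id = "a",
    date = as.Date(c("2019-09-02", "2019-09-03", "2019-09-09")),
    has_events = TRUE, has_visits = TRUE, workday = TRUE,
    hours_during = c(1, 2, 4), hours_outside = c(0.5, 0.5, 1),
    n_during = 1L, n_outside = 1L
  )
  wk <- aggregate_weekly(daily)
  expect_equal(wk$week, c("2019-W36", "2019-W37"))
  expect_equal(wk$hours_during, c(3, 4))
  expect_equal(wk$n_days, c(2L, 1L))

  md <- simulate_model_data(n_providers = 20, n_days = 15, seed = 21)
  fit <- suppressMessages(
    fit_ehr_mixed(md$daily, md$roster,
                  ehr_model_spec("outside", aggregation = "weekly")))
  expect_equal(fit$varcomp$group[1], "week")
  r2 <- r2_partition(fit)
  expect_equal(r2[["r2_fixed"]] + r2[["r2_random"]], r2[["r2_total"]],
               tolerance = 0.1)
})

test_that("model spec guards its design", {
  expect_true("during_minutes" %in% ehr_model_spec("outside")$fixed_terms)
  expect_false("during_minutes" %in% ehr_model_spec("during")$fixed_terms)
  expect_false("during_minutes" %in% ehr_model_spec("total")$fixed_terms)
  md <- simulate_model_data(n_providers = 1, n_days = 10, seed = 2)
  expect_error(
    fit_ehr_mixed(md$daily, md$roster, ehr_model_spec("during")),
    ">= 2 providers")
})

test_that("normality check recommends transforms only for skewed data", {
  withr::local_seed(99)
  normal <- rnorm(1000)
  nc <- normality_check(normal)
  expect_equal(nc$recommended_transform, "none")
  expect_lt(abs(nc$skewness), 0.5)
  skewed <- rexp(1000)
  nc2 <- normality_check(skewed)
  expect_equal(nc2$recommended_transform, "log1p")
  nc3 <- normality_check(rep(1, 50))
  expect_true(nc3$degenerate)
})
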