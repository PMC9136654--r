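# synthetic_data: seedable generator of a full synthetic study month —
# roster, visit schedules, action vocabulary/map, and access-log event
# streams — with ground truth for recovery testing.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults describe a single-month primary-care cohort: 56 physicians over
#' the weekdays of September 2019; per-workday EHR time budgets of mean
#' 4.4 h during and 0.8 h outside scheduled clinic hours (each decomposed
#' into a between-physician and a within-physician SD whose sum of squares
#' matches per-workday SDs of 2.0 and 0.8 h; outside draws are floored at
#' zero at both levels, so a fraction of physicians never work outside
#' clinic hours); 9 twenty-minute visits per half-day session (08:30-11:30,
#' 13:30-16:30, i.e. 6 scheduled hours per clinic day); a 290-code action
#' vocabulary split 161/64/34/19/6/6 across review/documentation/inbox/
#' orders/login/logout; segment-specific category time shares; log-normal
#' inter-event gaps with mean 13 s renormalized to each block's budget;
#' occasional injected idle gaps; evening (18:00) and weekend activity
#' tails.
#'
#' @param n_physicians Cohort size before exclusions.
#' @param month_start,month_end Study period (calendar dates).
#' @param p_workday Probability a physician holds clinic on a weekday.
#' @param during_mean,during_sd_between,during_sd_within Hours during
#'   clinic windows per workday: cohort mean, between-physician SD,
#'   day-level SD.
#' @param outside_mean,outside_sd_between,outside_sd_within Same for hours
#'   outside clinic windows (floored at 0).
#' @param during_share,outside_share Category time shares over the six
#'   clinical categories, per segment; each must sum to 1.
#' @param category_codes Named integer vector of vocabulary sizes per
#'   clinical category.
#' @param visits_per_session,visit_minutes Visits per half-day block and
#'   visit length.
#' @param gap_mean_s,gap_sdlog Mean inter-event gap (seconds) and log-scale
#'   SD of the log-normal gap distribution.
#' @param idle_rate Per clinic-day probability of injecting one idle gap
#'   (> idle cutoff) inside a window.
#' @param idle_cutoff_min Idle cutoff the generator respects when capping
#'   gaps (minutes).
#' @param weekend_p Probability an outside-hours user is active on a given
#'   weekend day.
#' @param age_mean,age_sd,service_mean,service_sd,fte_mean,fte_sd,cfte_mean,cfte_sd,p_male
#'   Roster demographics.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_physicians = 56,
                       month_start = as.Date("2019-09-01"),
                       month_end = as.Date("2019-09-30"),
                       p_workday = 0.91,
                       during_mean = 4.4,
                       during_sd_between = 1.8,
                       during_sd_within = 0.87,
                       outside_mean = 0.8,
                       outside_sd_between = 0.7,
                       outside_sd_within = 0.39,
                       during_share = c(review = 3.13, documentation = 0.28,
                                        inbox = 0.52, orders = 0.12,
                                        login = 0.03, logout = 0.28) / 4.36,
                       outside_share = c(review = 0.59, documentation = 0.05,
                                         inbox = 0.08, orders = 0.01,
                                         login = 0.01, logout = 0.02) / 0.76,
                       category_codes = c(review = 161L, documentation = 64L,
                                          inbox = 34L, orders = 19L,
                                          login = 6L, logout = 6L),
                       visits_per_session = 9L,
                       visit_minutes = 20,
                       gap_mean_s = 13,
                       gap_sdlog = 1,
                       idle_rate = 0.1,
                       idle_cutoff_min = 15,
                       weekend_p = 0.1,
                       age_mean = 45.6, age_sd = 9.9,
                       service_mean = 10.1, service_sd = 7.6,
                       fte_mean = 0.8, fte_sd = 0.2,
                       cfte_mean = 0.5, cfte_sd = 0.2,
                       p_male = 12 / 56,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_physicians >= 1, month_end >= month_start,
            all(names(cfg$during_share) == CLINICAL_CATEGORIES),
            all(names(cfg$outside_share) == CLINICAL_CATEGORIES),
            all(names(cfg$category_codes) == CLINICAL_CATEGORIES),
            all(cfg$category_codes > 0),
            abs(sum(cfg$during_share) - 1) < 1e-6,
            abs(sum(cfg$outside_share) - 1) < 1e-6,
            during_sd_between >= 0, during_sd_within >= 0,
            outside_sd_between >= 0, outside_sd_within >= 0,
            gap_mean_s > 0, gap_sdlog >= 0, idle_cutoff_min > 0,
            p_workday >= 0, p_workday <= 1, weekend_p >= 0, weekend_p <= 1)
  structure(cfg, class = "sim_config")
}

#' Default synthetic action-category map
#'
#' Builds the package's shipped action vocabulary: `sum(category_codes)`
#' synthetic codes (default 290) named by category prefix and rank, with
#' the conceptual category given by the fixed clinical-to-conceptual
#' alignment. This map is synthetic — the original study's code-level
#' mapping is not public — and the login/logout split (default 6/6) is
#' likewise a synthetic choice.
#'
#' @param category_codes Named integer vector of codes per clinical
#'   category (default as in [sim_config()]).
#' @return A tibble `action_code`, `clinical_category`,
#'   `conceptual_category`.
#' @export
default_action_map <- function(category_codes = c(review = 161L,
                                                  documentation = 64L,
                                                  inbox = 34L, orders = 19L,
                                                  login = 6L, logout = 6L)) {
  stopifnot(all(names(category_codes) %in% CLINICAL_CATEGORIES),
            all(category_codes > 0))
  prefix <- c(review = "REV", documentation = "DOC", inbox = "INB",
              orders = "ORD", login = "LGI", logout = "LGO")
  cats <- rep(names(category_codes), category_codes)
  code <- sprintf("%s_%03d", prefix[cats],
                  unlist(lapply(category_codes, seq_len), use.names = FALSE))
  tibble(action_code = code, clinical_category = cats,
         conceptual_category = unname(CONCEPTUAL_MAP[cats]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sim_roster <- function(cfg) {
  n <- cfg$n_physicians
  tibble(
    physician_id = sprintf("P%03d", seq_len(n)),
    age = round(clamp(rnorm(n, cfg$age_mean, cfg$age_sd), 30, 69)),
    sex = ifelse(runif(n) < cfg$p_male, "male", "female"),
    service_years = round(clamp(rnorm(n, cfg$service_mean, cfg$service_sd),
                                0.3, 33), 1),
    fte = round(clamp(rnorm(n, cfg$fte_mean, cfg$fte_sd), 0.5, 1), 2),
    cfte = NA_real_,
    employment_status = "regular"
  ) |>
    mutate(cfte = pmin(.data$fte,
                       round(clamp(rnorm(n, cfg$cfte_mean, cfg$cfte_sd),
                                   0.1, 0.9), 2)))
}

# Scale per-block gap draws to the block budget, then cap at the idle
# cutoff and redistribute the shortfall over uncapped gaps. `block` must be
# integer ids 1..n_blocks with every block represented, so rowsum() rows are
# positional.
scale_and_cap_gaps <- function(g, block, budget_by_block, cutoff_s) {
  blocksum <- rowsum(g, block)[, 1L]
  g <- g * (budget_by_block / blocksum)[block]
  for (i in 1:3) {
    over <- g > cutoff_s
    if (!any(over)) break
    capped <- pmin(g, cutoff_s)
    deficit <- budget_by_block - rowsum(capped, block)[, 1L]
    w <- ifelse(over, 0, g)
    wsum <- rowsum(w, block)[, 1L]
    add <- ifelse(wsum[block] > 0, w * (deficit[block] / wsum[block]), 0)
    g <- capped + add
  }
  pmin(g, cutoff_s)
}

#' Simulate a synthetic study cohort
#'
#' Generates the four pipeline inputs (roster, scheduled visits, action
#' map, access log) plus a ground-truth record, per the configuration. For
#' every clinic physician-day, target during/outside time budgets are
#' drawn, clinic windows are filled with event trains whose inter-event
#' gaps sum to the during budget (all gaps at or below the idle cutoff,
#' except injected idle gaps), and outside budgets are placed in evening
#' and weekend slots. Budgets that exceed the available window capacity are
#' truncated, with one summary warning. Identical seeds give identical
#' output.
#'
#' @param config A [sim_config()].
#' @return An `ehr_simulation` list: `roster`, `visits`, `action_map`,
#'   `access_log` tibbles, plus `ground_truth` (per-day true budgets,
#'   per-physician latent means, cohort bookkeeping) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::local_seed(cfg$seed)

  roster <- sim_roster(cfg)
  ids <- roster$physician_id
  n <- length(ids)

  all_dates <- seq(cfg$month_start, cfg$month_end, by = "day")
  dow <- as.POSIXlt(all_dates)$wday
  weekdays_ <- all_dates[dow %in% 1:5]
  weekends_ <- all_dates[dow %in% c(0, 6)]

  # Date -> POSIXct midnight on the clinic clock (length-0 safe)
  day0 <- function(d) as.POSIXct(as.numeric(d) * 86400,
                                 origin = "1970-01-01", tz = EHR_TZ)

  # clinic days -----------------------------------------------------------
  grid <- tidyr::expand_grid(physician_id = ids, date = weekdays_)
  grid <- grid[runif(nrow(grid)) < cfg$p_workday, , drop = FALSE]

  # visits: two half-day sessions per clinic day
  session_starts_min <- c(8.5 * 60, 13.5 * 60)
  vis <- tidyr::expand_grid(grid,
                            session = session_starts_min,
                            slot = seq_len(cfg$visits_per_session) - 1L) |>
    mutate(start = day0(.data$date) +
             60 * (.data$session + .data$slot * cfg$visit_minutes),
           end = .data$start + 60 * cfg$visit_minutes) |>
    select("physician_id", "start", "end") |>
    arrange(.data$physician_id, .data$start)

  # latent per-physician means, then per-day budgets -----------------------
  mu_d <- clamp(rnorm(n, cfg$during_mean, cfg$during_sd_between), 0.5, 7.8)
  mu_o <- pmax(0, rnorm(n, cfg$outside_mean, cfg$outside_sd_between))
  names(mu_d) <- names(mu_o) <- ids

  margin_s <- 30 * 60
  session_len_s <- cfg$visits_per_session * cfg$visit_minutes * 60
  cap_half <- session_len_s + 2 * margin_s - 60 # per-window fill capacity
  cap_during <- 2 * cap_half
  cap_outside <- 5 * 3600 - 60
  cutoff_s <- cfg$idle_cutoff_min * 60

  pidx <- match(grid$physician_id, ids)
  b_d <- rnorm(nrow(grid), mu_d[pidx], cfg$during_sd_within) * 3600
  b_o <- pmax(0, rnorm(nrow(grid), mu_o[pidx], cfg$outside_sd_within)) * 3600
  b_o[mu_o[pidx] == 0] <- 0
  n_trunc <- sum(b_d > cap_during) + sum(b_o > cap_outside)
  b_d <- clamp(b_d, 0, cap_during)
  b_o <- pmin(b_o, cap_outside)

  # weekend activity ------------------------------------------------------
  wk <- tidyr::expand_grid(physician_id = ids[mu_o > 0], date = weekends_)
  wk <- wk[runif(nrow(wk)) < cfg$weekend_p, , drop = FALSE]
  wk_b <- pmax(0, rnorm(nrow(wk),
                        mu_o[match(wk$physician_id, ids)],
                        cfg$outside_sd_within)) * 3600
  wk <- wk[wk_b > 1, , drop = FALSE]
  wk_b <- wk_b[wk_b > 1]

  # block table: one row per contiguous event train ------------------------
  frac <- clamp(runif(nrow(grid), 0.35, 0.65), 0, 1)
  b_m <- pmin(b_d * frac, cap_half)
  b_a <- b_d - b_m
  overflow <- pmax(b_a - cap_half, 0)
  b_a <- b_a - overflow
  b_m <- b_m + overflow

  mk_block <- function(g, start_s, budget, type) {
    tibble(physician_id = g$physician_id, date = g$date,
           start = day0(g$date) + start_s, budget_s = budget, type = type)
  }
  win_start_m <- 8.5 * 3600 - margin_s   # 08:00
  win_start_a <- 13.5 * 3600 - margin_s  # 13:00
  blocks <- bind_rows(
    mk_block(grid, win_start_m, b_m, "morning"),
    mk_block(grid, win_start_a, b_a, "afternoon"),
    mk_block(grid, 18 * 3600, b_o, "evening"),
    mk_block(wk, 9 * 3600, wk_b, "weekend")
  ) |>
    filter(.data$budget_s > 1) |>
    arrange(.data$physician_id, .data$start)

  # idle-gap injection into morning blocks with spare capacity
  idle_extra <- rep(0, nrow(blocks))
  cand <- blocks$type == "morning" &
    (cap_half - blocks$budget_s) > 2400 &
    runif(nrow(blocks)) < cfg$idle_rate
  idle_extra[cand] <- cutoff_s + runif(sum(cand), 60, 540)
  blocks$idle_extra <- idle_extra

  # event trains ----------------------------------------------------------
  n_blocks <- nrow(blocks)
  n_gaps <- pmax(1L, as.integer(round(blocks$budget_s / cfg$gap_mean_s)))
  block_row <- rep(seq_len(n_blocks), n_gaps)
  meanlog <- log(cfg$gap_mean_s) - cfg$gap_sdlog^2 / 2
  g <- rlnorm(sum(n_gaps), meanlog, cfg$gap_sdlog)
  g <- scale_and_cap_gaps(g, block_row, blocks$budget_s, cutoff_s)

  # inject the idle gap after each selected block's first event: the first
  # event then carries the long (> cutoff) delta and later events shift
  first_of_block <- !duplicated(block_row)
  g_offset <- grouped_cumsum(g, block_row) - g +
    ifelse(first_of_block, 0, blocks$idle_extra[block_row])
  ev_time <- as.numeric(blocks$start)[block_row] + g_offset

  # trailing closer event per block (duration = gap to next train)
  trail_time <- as.numeric(blocks$start) +
    unname(rowsum(g, block_row)[, 1L]) + blocks$idle_extra

  ev <- tibble(
    user_id = c(blocks$physician_id[block_row], blocks$physician_id),
    timestamp_n = unname(c(ev_time, trail_time)),
    segment = c(blocks$type[block_row], blocks$type) %in%
      c("morning", "afternoon")
  )

  # action codes drawn by segment-specific category time share -------------
  action_map <- default_action_map(cfg$category_codes)
  codes_by_cat <- split(action_map$action_code,
                        action_map$clinical_category)
  zipf <- function(k) (1 / seq_len(k)) / sum(1 / seq_len(k))
  cat_idx <- integer(nrow(ev))
  idx_during <- which(ev$segment)
  idx_outside <- which(!ev$segment)
  cat_idx[idx_during] <- sample.int(6L, length(idx_during), replace = TRUE,
                                    prob = cfg$during_share)
  cat_idx[idx_outside] <- sample.int(6L, length(idx_outside),
                                     replace = TRUE,
                                     prob = cfg$outside_share)
  cat_name <- CLINICAL_CATEGORIES[cat_idx]
  code <- character(nrow(ev))
  for (cc in CLINICAL_CATEGORIES) {
    sel <- which(cat_name == cc)
    pool <- codes_by_cat[[cc]]
    code[sel] <- sample(pool, length(sel), replace = TRUE,
                        prob = zipf(length(pool)))
  }

  access_log <- tibble(
    user_id = ev$user_id,
    timestamp = as.POSIXct(round(ev$timestamp_n), origin = "1970-01-01",
                           tz = EHR_TZ),
    action_code = code,
    source = NA_character_
  )
  access_log <- access_log[order(access_log$user_id,
                                 access_log$timestamp), , drop = FALSE]

  if (n_trunc > 0) {
    warn(sprintf("%d daily time budget(s) exceeded window capacity and were truncated",
                 n_trunc))
  }

  # ground truth ----------------------------------------------------------
  truth_daily <- bind_rows(
    tibble(physician_id = grid$physician_id, date = grid$date,
           true_during_h = b_d / 3600, true_outside_h = b_o / 3600),
    tibble(physician_id = wk$physician_id, date = wk$date,
           true_during_h = 0, true_outside_h = wk_b / 3600)
  ) |>
    arrange(.data$physician_id, .data$date)
  truth_phys <- truth_daily |>
    group_by(.data$physician_id) |>
    summarise(n_days = n(), mean_during = mean(.data$true_during_h),
              mean_outside = mean(.data$true_outside_h), .groups = "drop")
  ground_truth <- list(
    daily = truth_daily,
    physicians = truth_phys,
    cohort = list(
      n_physicians = n,
      n_days = nrow(truth_daily),
      mean_during = mean(truth_phys$mean_during),
      mean_outside = mean(truth_phys$mean_outside)
    ),
    planned_clinic_hours = nrow(grid) * 2 * session_len_s / 3600,
    n_truncated = n_trunc
  )

  structure(list(roster = roster, visits = vis, action_map = action_map,
                 access_log = access_log, ground_truth = ground_truth,
                 config = cfg),
            class = "ehr_simulation")
}

#' Write a simulated study to disk
#'
#' Writes the four observed input CSVs (`roster.csv`, `visits.csv`,
#' `action_map.csv`, `access_log.csv`) and the sidecar
#' `ground_truth.json`. Ground truth is never mixed into the observed
#' files.
#'
#' @param sim An `ehr_simulation` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ehr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ehr_csv(sim$roster, file.path(dir, "roster.csv"))
  write_ehr_csv(sim$visits, file.path(dir, "visits.csv"))
  write_ehr_csv(sim$action_map, file.path(dir, "action_map.csv"))
  write_ehr_csv(sim$access_log, file.path(dir, "access_log.csv"))
  gt <- sim$ground_truth
  gt$daily$date <- as.character(gt$daily$date)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate daily summaries with known model structure
#'
#' Generates a daily-summary table whose outcome follows the mixed-model
#' data-generating process exactly: fixed linear predictor plus crossed
#' provider and day random intercepts plus residual noise, with every
#' parameter known. Used for parameter-recovery testing of
#' [fit_ehr_mixed()].
#'
#' @param n_providers,n_days Design size (full provider-by-day grid).
#' @param beta Named fixed coefficients; must include `(Intercept)`, `age`,
#'   `gender_female`, `cfte`, and — for the outside model —
#'   `during_minutes`.
#' @param sd_provider,sd_day,sd_resid Random-intercept and residual SDs.
#' @param outcome Which outcome column the draws populate (`"outside"`,
#'   `"during"`, or `"total"`).
#' @param seed Integer seed.
#' @return A list: `daily` (summary table), `roster`, and `truth` (the
#'   generating parameters).
#' @export
simulate_model_data <- function(n_providers = 56, n_days = 19,
                                beta = c("(Intercept)" = 2.2,
                                         during_minutes = -0.18 / 60,
                                         age = -0.004, gender_female = -0.8,
                                         cfte = 0.67),
                                sd_provider = 0.8, sd_day = 0.24,
                                sd_resid = 0.6,
                                outcome = c("outside", "during", "total"),
                                seed = 1L) {
  outcome <- match.arg(outcome)
  withr::local_seed(seed)
  ids <- sprintf("P%03d", seq_len(n_providers))
  roster <- tibble(
    physician_id = ids,
    age = round(clamp(rnorm(n_providers, 45.6, 9.9), 30, 69)),
    sex = ifelse(runif(n_providers) < 12 / 56, "male", "female"),
    service_years = round(clamp(rnorm(n_providers, 10.1, 7.6), 0.3, 33), 1),
    fte = round(clamp(rnorm(n_providers, 0.8, 0.2), 0.5, 1), 2),
    cfte = NA_real_,
    employment_status = "regular"
  ) |>
    mutate(cfte = pmin(.data$fte,
                       round(clamp(rnorm(n_providers, 0.5, 0.2), 0.1, 0.9),
                             2)))
  wd <- seq(as.Date("2019-09-02"), by = "day", length.out = n_days * 2)
  wd <- wd[as.POSIXlt(wd)$wday %in% 1:5][seq_len(n_days)]
  grid <- tidyr::expand_grid(physician_id = ids, date = wd)
  u <- structure(rnorm(n_providers, 0, sd_provider), names = ids)
  v <- structure(rnorm(n_days, 0, sd_day), names = as.character(wd))
  hours_during <- pmax(0, rnorm(nrow(grid), 4.4, 2.0))
  r <- roster[match(grid$physician_id, roster$physician_id), ]
  eta <- beta[["(Intercept)"]] +
    beta[["age"]] * r$age +
    beta[["gender_female"]] * as.numeric(r$sex == "female") +
    beta[["cfte"]] * r$cfte
  if (outcome == "outside") {
    if (!"during_minutes" %in% names(beta)) {
      stop_input("beta must include during_minutes for the outside model")
    }
    eta <- eta + beta[["during_minutes"]] * hours_during * 60
  }
  y <- eta + u[grid$physician_id] + v[as.character(grid$date)] +
    rnorm(nrow(grid), 0, sd_resid)
  daily <- tibble(
    physician_id = grid$physician_id, date = grid$date,
    has_events = TRUE, has_visits = TRUE, workday = TRUE,
    hours_during = switch(outcome, outside = hours_during, during = y,
                          total = y),
    hours_outside = if (outcome == "outside") y else 0,
    n_during = 0L, n_outside = 0L
  )
  list(daily = daily, roster = roster,
       truth = list(beta = beta, sd_provider = sd_provider, sd_day = sd_day,
                    sd_resid = sd_resid, outcome = outcome))
}
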