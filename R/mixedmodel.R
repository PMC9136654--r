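# mixedmodel: crossed random-effects models of daily/weekly EHR hours and
# the fixed/random/total R-squared partition.

#' Specify a mixed model of EHR hours
#'
#' Declares one of the three outcome models: hours during scheduled clinic
#' hours, hours outside, or total hours, on daily or ISO-week aggregated
#' data. Fixed effects are physician age (years), gender (indicator for
#' female, reference male), and clinical FTE; the outside-hours model
#' additionally — and only it — adjusts for EHR time during clinic hours,
#' entered in minutes. Random intercepts are crossed: provider and calendar
#' day (or ISO week under weekly aggregation).
#'
#' @param outcome `"during"`, `"outside"`, or `"total"`.
#' @param aggregation `"daily"` (default) or `"weekly"`.
#' @param transform `"none"` (default) or `"log1p"` applied to the outcome.
#' @return An `ehr_model_spec` list.
#' @export
ehr_model_spec <- function(outcome = c("during", "outside", "total"),
                           aggregation = c("daily", "weekly"),
                           transform = c("none", "log1p")) {
  outcome <- match.arg(outcome)
  fixed <- c("age", "gender_female", "cfte")
  if (outcome == "outside") fixed <- c("during_minutes", fixed)
  structure(list(outcome = outcome,
                 aggregation = match.arg(aggregation),
                 transform = match.arg(transform),
                 fixed_terms = fixed,
                 random_terms = c("provider", "time")),
            class = "ehr_model_spec")
}

#' Aggregate daily summaries to ISO weeks
#'
#' Sums hours per physician and ISO-8601 week (week-based year and week
#' number). Only workday rows contribute.
#'
#' @param daily Daily summary from [summarize_daily()].
#' @return A tibble `physician_id`, `week`, `n_days`, `hours_during`,
#'   `hours_outside`.
#' @export
aggregate_weekly <- function(daily) {
  require_columns(daily, c("physician_id", "date", "workday",
                           "hours_during", "hours_outside"), "daily")
  daily |>
    filter(.data$workday) |>
    mutate(week = format(.data$date, "%G-W%V")) |>
    group_by(.data$physician_id, .data$week) |>
    summarise(n_days = n(),
              hours_during = sum(.data$hours_during),
              hours_outside = sum(.data$hours_outside),
              .groups = "drop")
}

build_model_frame <- function(daily, roster, spec) {
  require_columns(roster, c("physician_id", "age", "sex", "cfte"), "roster")
  if (spec$aggregation == "weekly") {
    base <- aggregate_weekly(daily) |> rename(time_id = "week")
  } else {
    base <- daily |>
      filter(.data$workday) |>
      mutate(time_id = as.character(.data$date)) |>
      select("physician_id", "time_id", "hours_during", "hours_outside")
  }
  mf <- base |>
    mutate(hours_total = .data$hours_during + .data$hours_outside,
           during_minutes = .data$hours_during * 60,
           outcome = switch(spec$outcome,
                            during = .data$hours_during,
                            outside = .data$hours_outside,
                            total = .data$hours_total)) |>
    left_join(roster |>
                mutate(gender_female =
                         as.numeric(.data$sex == "female")) |>
                select("physician_id", "age", "gender_female", "cfte"),
              by = "physician_id")
  if (spec$transform == "log1p") mf$outcome <- log1p(mf$outcome)
  need <- c("outcome", spec$fixed_terms)
  if (!all(complete.cases(mf[need]))) {
    stop_input("model covariates or outcome contain missing values")
  }
  mf
}

#' Fit a crossed random-effects model of EHR hours
#'
#' Fits the declared model by restricted maximum likelihood with crossed
#' random intercepts for provider and day (or ISO week), via
#' [lme4::lmer()]. With `random = character(0)` the model reduces to
#' ordinary least squares on the same fixed effects. A singular fit (a
#' variance component estimated at the boundary zero) is flagged, not an
#' error; a constant outcome yields a degenerate result with all variance
#' components zero and the intercept equal to the constant.
#'
#' @param daily Daily summary from [summarize_daily()].
#' @param roster Physician roster supplying `age`, `sex`, `cfte`.
#' @param spec An [ehr_model_spec()].
#' @param random Random intercept terms to include, a subset of
#'   `c("provider", "time")` (default both, crossed).
#' @return An `ehr_mixed_fit` with coefficient table, variance components,
#'   and the R-squared partition; see [tidy()], [glance()],
#'   [r2_partition()].
#' @export
fit_ehr_mixed <- function(daily, roster, spec = ehr_model_spec("outside"),
                          random = c("provider", "time")) {
  stopifnot(inherits(spec, "ehr_model_spec"))
  random <- intersect(random, c("provider", "time"))
  mf <- build_model_frame(daily, roster, spec)
  if (length(random) > 0) {
    if (n_distinct(mf$physician_id) < 2L) {
      stop_input("need >= 2 providers to fit random effects")
    }
    if (n_distinct(mf$time_id) < 2L) {
      stop_input("need >= 2 days/weeks to fit random effects")
    }
  }
  time_label <- if (spec$aggregation == "weekly") "week" else "day"

  if (var(mf$outcome) == 0) {
    coefs <- tibble(term = c("(Intercept)", spec$fixed_terms),
                    estimate = c(mf$outcome[1L],
                                 rep(0, length(spec$fixed_terms))),
                    std_error = NA_real_)
    varcomp <- tibble(group = c(time_label, "provider", "residual"),
                      variance = 0, sd = 0)
    out <- list(spec = spec, fit = NULL, coefficients = coefs,
                varcomp = varcomp, n_obs = nrow(mf),
                var_fixed = 0, singular = TRUE, degenerate = TRUE,
                r2 = c(r2_fixed = NA_real_, r2_random = NA_real_,
                       r2_total = NA_real_))
    return(structure(out, class = "ehr_mixed_fit"))
  }

  rhs <- paste(spec$fixed_terms, collapse = " + ")
  ran <- c(provider = "(1 | physician_id)", time = "(1 | time_id)")[random]
  if (length(ran) > 0) {
    fml <- as.formula(paste("outcome ~", rhs, "+",
                            paste(ran, collapse = " + ")))
    # predictors keep their natural units (minutes vs FTE fractions), so
    # the scale heuristic is disabled rather than rescaling coefficients
    fit <- lme4::lmer(fml, data = mf, REML = TRUE,
                      control = lme4::lmerControl(check.scaleX = "ignore"))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get_var <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v) == 0L) 0 else v[1L]
    }
    varcomp <- tibble(
      group = c(time_label, "provider", "residual"),
      variance = c(if ("time" %in% random) get_var("time_id") else 0,
                   if ("provider" %in% random) get_var("physician_id")
                   else 0,
                   get_var("Residual"))
    )
    singular <- lme4::isSingular(fit)
  } else {
    fml <- as.formula(paste("outcome ~", rhs))
    fit <- lm(fml, data = mf)
    fe <- coef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    varcomp <- tibble(group = c(time_label, "provider", "residual"),
                      variance = c(0, 0, summary(fit)$sigma^2))
    singular <- FALSE
  }
  varcomp$sd <- sqrt(varcomp$variance)
  coefs <- tibble(term = names(fe), estimate = unname(fe),
                  std_error = unname(se))

  # aliased terms (e.g. a constant covariate) are dropped by the fitter;
  # they contribute nothing to the fixed linear predictor
  X <- model.matrix(as.formula(paste("~", rhs)), data = mf)
  fe_vec <- setNames(numeric(ncol(X)), colnames(X))
  common <- intersect(names(fe), colnames(X))
  fe_vec[common] <- ifelse(is.na(fe[common]), 0, fe[common])
  eta <- drop(X %*% fe_vec)
  var_fixed <- var(eta)

  out <- list(spec = spec, fit = fit, coefficients = coefs,
              varcomp = varcomp, n_obs = nrow(mf), var_fixed = var_fixed,
              singular = singular, degenerate = FALSE, r2 = NULL)
  out$r2 <- r2_partition(structure(out, class = "ehr_mixed_fit"))
  structure(out, class = "ehr_mixed_fit")
}

#' Arithmetic core of the R-squared partition
#'
#' Given the variance of the fixed-effect linear predictor, the summed
#' random-intercept variance components, and the residual variance, returns
#' the fixed/random/total percent shares of total outcome variance, where
#' the total variance is their sum.
#'
#' @param var_fixed Variance of the fixed-effect linear predictor.
#' @param var_random Sum of random-intercept variance components.
#' @param var_residual Residual variance.
#' @return Named numeric: `r2_fixed`, `r2_random`, `r2_total` (percent).
#' @export
#' @examples
#' r2_components(1, 4, 5) # 10, 40, 50
r2_components <- function(var_fixed, var_random, var_residual) {
  total <- var_fixed + var_random + var_residual
  if (!is.finite(total) || total <= 0) {
    stop_input("total outcome variance is zero; R2 partition undefined")
  }
  c(r2_fixed = 100 * var_fixed / total,
    r2_random = 100 * var_random / total,
    r2_total = 100 * (var_fixed + var_random) / total)
}

#' Fixed/random/total R-squared partition of a fitted model
#'
#' Decomposes explained variance in the style of marginal/conditional
#' R-squared: the fixed share is the variance of the fixed-effect linear
#' predictor over the total variance (fixed predictor + provider + day +
#' residual variance); the random share is the summed random-intercept
#' components over the same total; the total is their sum, so the partition
#' is additive by construction.
#'
#' @param x An `ehr_mixed_fit`.
#' @return Named numeric: `r2_fixed`, `r2_random`, `r2_total` (percent).
#' @export
r2_partition <- function(x) {
  stopifnot(inherits(x, "ehr_mixed_fit"))
  if (isTRUE(x$degenerate)) {
    stop_input("total outcome variance is zero; R2 partition undefined")
  }
  vr <- sum(x$varcomp$variance[x$varcomp$group != "residual"])
  ve <- x$varcomp$variance[x$varcomp$group == "residual"]
  r2_components(x$var_fixed, vr, ve)
}

#' Residual normality diagnostic
#'
#' Reports moment-based skewness and excess kurtosis and a quantile
#' comparison of the standardized sample against the standard normal, and
#' recommends a `log1p` transform when skewness exceeds the threshold. The
#' recommendation is advisory; nothing is transformed automatically.
#' Constant input is flagged as degenerate.
#'
#' @param x Numeric vector of residuals (or an `ehr_mixed_fit`, whose
#'   residuals are used).
#' @param skew_threshold Skewness above which `log1p` is recommended
#'   (default 1).
#' @return A list with `n`, `skewness`, `excess_kurtosis`, a `quantiles`
#'   tibble (standardized sample vs normal), `degenerate`, and
#'   `recommended_transform` (`"none"` or `"log1p"`).
#' @export
normality_check <- function(x, skew_threshold = 1) {
  if (inherits(x, "ehr_mixed_fit")) {
    if (is.null(x$fit)) {
      return(list(n = x$n_obs, skewness = NA_real_,
                  excess_kurtosis = NA_real_, quantiles = NULL,
                  degenerate = TRUE, recommended_transform = "none"))
    }
    x <- residuals(x$fit)
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || sd(x) == 0) {
    return(list(n = n, skewness = NA_real_, excess_kurtosis = NA_real_,
                quantiles = NULL, degenerate = TRUE,
                recommended_transform = "none"))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2 - 3
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  q <- tibble(prob = probs,
              sample = as.numeric(quantile((x - m) / sqrt(m2), probs)),
              normal = qnorm(probs))
  list(n = n, skewness = skew, excess_kurtosis = kurt, quantiles = q,
       degenerate = FALSE,
       recommended_transform = if (skew > skew_threshold) "log1p"
       else "none")
}

#' @exportS3Method base::print
print.ehr_mixed_fit <- function(x, ...) {
  cat(sprintf("Crossed random-effects model: %s EHR hours (%s)\n",
              x$spec$outcome, x$spec$aggregation))
  if (x$degenerate) {
    cat("  degenerate fit: constant outcome\n")
    return(invisible(x))
  }
  cat(sprintf("  observations: %d%s\n", x$n_obs,
              if (x$singular) "   [singular fit]" else ""))
  cat("  fixed effects:\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("    %-16s %8.3f (SE %.3f)\n", cf$term[i], cf$estimate[i],
                cf$std_error[i]))
  }
  cat("  random-effect variances:\n")
  vc <- x$varcomp
  for (i in seq_len(nrow(vc))) {
    cat(sprintf("    %-10s %8.3f (SD %.3f)\n", vc$group[i],
                vc$variance[i], vc$sd[i]))
  }
  cat(sprintf("  R2 (%%): fixed %.1f, random %.1f, total %.1f\n",
              x$r2[["r2_fixed"]], x$r2[["r2_random"]],
              x$r2[["r2_total"]]))
  invisible(x)
}

#' Tidy a fitted EHR mixed model
#'
#' @param x An `ehr_mixed_fit`.
#' @param effects `"fixed"` (coefficients), `"ran_pars"` (variance
#'   components), or both (default).
#' @param ... Unused.
#' @return A tibble with an `effect` column and, per row, either a fixed
#'   coefficient with its SE or a variance component with its SD.
#' @export
tidy.ehr_mixed_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- x$coefficients |> mutate(effect = "fixed")
  }
  if ("ran_pars" %in% effects) {
    out$ran <- x$varcomp |>
      rename(term = "group", estimate = "variance") |>
      mutate(effect = "ran_pars", std_error = NA_real_) |>
      select("term", "estimate", "std_error", "sd")
    out$ran$effect <- "ran_pars"
  }
  bind_rows(out) |> select("effect", dplyr::everything())
}

#' One-row overview of a fitted EHR mixed model
#'
#' @param x An `ehr_mixed_fit`.
#' @param ... Unused.
#' @return A one-row tibble: outcome, aggregation, observations, the
#'   R-squared partition, and the singularity flag.
#' @export
glance.ehr_mixed_fit <- function(x, ...) {
  tibble(outcome = x$spec$outcome, aggregation = x$spec$aggregation,
         n_obs = x$n_obs,
         r2_fixed = x$r2[["r2_fixed"]],
         r2_random = x$r2[["r2_random"]],
         r2_total = x$r2[["r2_total"]],
         singular = x$singular)
}
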