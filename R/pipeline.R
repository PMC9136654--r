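# cli/pipeline: configuration, the end-to-end run, and the run manifest.

#' Pipeline configuration
#'
#' Every analysis choice left open by the method has an explicit,
#' overridable knob here; defaults are the package's documented defaults.
#'
#' @param idle_cutoff_min Idle cutoff in minutes ([filter_idle()]).
#' @param idle_policy `"remove"` or `"zero_duration"`.
#' @param margin_min Window margin in minutes ([build_clinic_windows()]).
#' @param straddle `"split"` or `"start"` ([segment_actions()]).
#' @param workday Workday rule ([summarize_daily()]).
#' @param unmapped Unmapped-code policy ([categorize_actions()]).
#' @param k_top Actions per category in the top-action table.
#' @param high_threshold_hours High-user threshold (hours).
#' @param admin_fraction Administrative fraction of nominal clinic hours.
#' @param planned_clinic_hours Total nominal clinic hours; `NULL` (default)
#'   derives it from the scheduled visit durations.
#' @param skew_threshold Skewness threshold for the residual-normality
#'   advisory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(idle_cutoff_min = 15,
                            idle_policy = c("remove", "zero_duration"),
                            margin_min = 30,
                            straddle = c("split", "start"),
                            workday = c("either", "events", "visits"),
                            unmapped = c("error", "bucket"),
                            k_top = 3,
                            high_threshold_hours = 1.5,
                            admin_fraction = 0.11,
                            planned_clinic_hours = NULL,
                            skew_threshold = 1) {
  structure(list(idle_cutoff_min = idle_cutoff_min,
                 idle_policy = match.arg(idle_policy),
                 margin_min = margin_min,
                 straddle = match.arg(straddle),
                 workday = match.arg(workday),
                 unmapped = match.arg(unmapped),
                 k_top = k_top,
                 high_threshold_hours = high_threshold_hours,
                 admin_fraction = admin_fraction,
                 planned_clinic_hours = planned_clinic_hours,
                 skew_threshold = skew_threshold),
            class = "pipeline_config")
}

as_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1L) reader(x)
  else if (is.data.frame(x)) as_tibble(x)
  else stop_input("%s must be a file path or a data frame", what)
}

#' Run the full access-log analysis pipeline
#'
#' Executes the whole analysis: cohort filtering, access-time estimation,
#' idle filtering, clinic-window construction, during/outside segmentation,
#' categorization, daily and cohort summaries, and the crossed
#' random-effects models (all three outcomes, daily and weekly
#' aggregation). When `out_dir` is given, writes `daily_summary.csv`,
#' `cohort_summary.csv`, `category_table.csv`, `top_actions.csv`,
#' `model_results.json`, and a `run_manifest.json` recording the
#' configuration (and its hash), input row counts, and exclusion/removal
#' tallies; a failed stage is recorded in the manifest before the error
#' propagates. Fixed inputs and configuration give byte-identical outputs.
#'
#' @param access_log,visits,roster,action_map Paths to the input CSVs or
#'   equivalent tibbles.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list: `cohort_filter`, `windows`, `actions` (segmented and
#'   categorized), `daily`, `cohort` (an `ehr_cohort_summary`), `models`
#'   (six `ehr_mixed_fit`s), and `manifest`.
#' @export
run_pipeline <- function(access_log, visits, roster, action_map,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config = unclass(config),
                   config_hash = rlang::hash(unclass(config)))
  stage <- "read_inputs"
  fail <- function(e) {
    manifest$failed_stage <- stage
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(manifest,
                           file.path(out_dir, "run_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "ehrwow_pipeline_error", parent = e)
  }
  out <- tryCatch({
    events <- as_input(access_log, read_access_log, "access_log")
    vis <- as_input(visits, read_visits, "visits")
    ros <- as_input(roster, read_roster, "roster")
    amap <- as_input(action_map, read_action_map, "action_map")
    manifest$rows <- list(access_log = nrow(events), visits = nrow(vis),
                          roster = nrow(ros), action_map = nrow(amap))

    stage <- "filter_cohort"
    cohort_filter <- filter_cohort(ros, vis)
    elig <- eligible_ids(cohort_filter)
    manifest$exclusions <- attr(cohort_filter, "exclusions")
    manifest$n_eligible <- length(elig)
    events <- filter(events, .data$user_id %in% elig)
    vis <- filter(vis, .data$physician_id %in% elig)
    ros_elig <- filter(ros, .data$physician_id %in% elig)

    stage <- "estimate_access_time"
    timed <- estimate_access_time(events)
    stage <- "filter_idle"
    timed <- filter_idle(timed, cutoff_min = config$idle_cutoff_min,
                         policy = config$idle_policy)
    manifest$idle_removed <- attr(timed, "n_removed")
    manifest$idle_removed_seconds <- attr(timed, "removed_seconds")
    manifest$n_retained <- nrow(timed)

    stage <- "build_windows"
    windows <- build_clinic_windows(vis, margin_min = config$margin_min)
    stage <- "segment_actions"
    seg <- segment_actions(timed, windows, straddle = config$straddle)
    stage <- "categorize"
    seg <- categorize_actions(seg, amap, unmapped = config$unmapped)

    stage <- "summarize"
    daily <- summarize_daily(seg, vis, workday = config$workday)
    planned <- config$planned_clinic_hours %||%
      sum(as.numeric(vis$end) - as.numeric(vis$start)) / 3600
    cohort <- summarize_cohort(
      daily, seg, k_top = config$k_top,
      high_threshold_hours = config$high_threshold_hours,
      planned_clinic_hours = planned,
      admin_fraction = config$admin_fraction)

    stage <- "fit_mixed"
    models <- list()
    for (agg in c("daily", "weekly")) {
      for (oc in c("during", "outside", "total")) {
        models[[paste(oc, agg, sep = "_")]] <-
          fit_ehr_mixed(daily, ros_elig, ehr_model_spec(oc, agg))
      }
    }

    list(cohort_filter = cohort_filter, windows = windows, actions = seg,
         daily = daily, cohort = cohort, models = models)
  }, error = fail)

  manifest$n_workdays <- out$cohort$n_workdays
  out$manifest <- manifest

  if (!is.null(out_dir)) {
    stage <- "write_outputs"
    tryCatch({
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ehr_csv(out$daily, file.path(out_dir, "daily_summary.csv"))
      write_ehr_csv(glance(out$cohort),
                    file.path(out_dir, "cohort_summary.csv"))
      write_ehr_csv(out$cohort$category_table,
                    file.path(out_dir, "category_table.csv"))
      write_ehr_csv(out$cohort$top_actions,
                    file.path(out_dir, "top_actions.csv"))
      results <- lapply(out$models, function(m) {
        nc <- normality_check(m, skew_threshold = config$skew_threshold)
        list(spec = unclass(m$spec),
             coefficients = m$coefficients,
             variance_components = m$varcomp,
             r2 = as.list(m$r2),
             n_obs = m$n_obs,
             singular = m$singular,
             diagnostics = list(
               skewness = nc$skewness,
               excess_kurtosis = nc$excess_kurtosis,
               recommended_transform = nc$recommended_transform))
      })
      jsonlite::write_json(results,
                           file.path(out_dir, "model_results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      jsonlite::write_json(out$manifest,
                           file.path(out_dir, "run_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, error = fail)
  }
  out
}
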