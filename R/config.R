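#' Pipeline configuration
#'
#' Assembles the screening, splitting and validation parameters used across
#' the pipeline into one validated list. Defaults mirror the published study
#' protocol: an 8 a.m.--9 p.m. day window, 90-minute zero-count non-wear
#' bouts with a 2-minute/100-cpm allowance, 546 wear minutes (70% of the
#' window) for a valid day, a 4-day/3-weekday/1-weekend valid week, a 4-MET
#' MVPA floor, a 70/30 calibration/validation split balanced across seasons,
#' 5,460 awake minutes per week and a 420 min/week activity guideline.
#'
#' @param n_participants Cohort size for simulation (default 148).
#' @param seed Integer seed for simulation and splitting.
#' @param window_start,window_end Daily monitoring window, `"HH:MM"`.
#' @param nonwear_min_bout,nonwear_allow_minutes,nonwear_allow_ceiling
#'   Non-wear rule parameters (minutes, minutes, cpm).
#' @param valid_day_minutes Minimum wear minutes for a valid day.
#' @param min_valid_days,min_weekday_valid,min_weekend_valid Week validity.
#' @param met_threshold MVPA floor in METs.
#' @param cutpoint_table Optional named age-to-cpm override table.
#' @param combine `"weighted"` (5/7 weekday + 2/7 weekend) or `"unweighted"`.
#' @param split_frac Calibration fraction of the sample.
#' @param stratify_by_season Balance the split within season strata.
#' @param coefficient_source `"fit"` (fit on the calibration split) or
#'   `"published"` (use [paq_reference_coefficients()], skip fitting).
#' @param awake_minutes_per_week Weekly awake-time base for minute conversion.
#' @param guideline_weekly_minutes Weekly MVPA guideline threshold.
#' @param output_dir Directory used by [run_simulate()] / [run_pipeline()].
#' @return A classed list (`paq_config`).
#' @export
paq_config <- function(n_participants = 148,
                       seed = 2009,
                       window_start = "08:00",
                       window_end = "21:00",
                       nonwear_min_bout = 90,
                       nonwear_allow_minutes = 2,
                       nonwear_allow_ceiling = 100,
                       valid_day_minutes = 546,
                       min_valid_days = 4,
                       min_weekday_valid = 3,
                       min_weekend_valid = 1,
                       met_threshold = 4,
                       cutpoint_table = NULL,
                       combine = "weighted",
                       split_frac = 0.70,
                       stratify_by_season = TRUE,
                       coefficient_source = c("fit", "published"),
                       awake_minutes_per_week = 5460,
                       guideline_weekly_minutes = 420,
                       output_dir = "paqcal-run") {
  assert_count(n_participants, "n_participants", lower = 0)
  assert_count(seed, "seed", lower = 0)
  assert_number(nonwear_min_bout, "nonwear_min_bout", lower = 1)
  assert_number(valid_day_minutes, "valid_day_minutes", lower = 0)
  assert_fraction(split_frac, "split_frac")
  assert_number(awake_minutes_per_week, "awake_minutes_per_week", lower = 1)
  coefficient_source <- match.arg(coefficient_source)
  combine <- match.arg(combine, c("weighted", "unweighted"))
  parse_clock(window_start, "window_start")
  parse_clock(window_end, "window_end")
  structure(list(
    n_participants = n_participants, seed = seed,
    window_start = window_start, window_end = window_end,
    nonwear_min_bout = nonwear_min_bout,
    nonwear_allow_minutes = nonwear_allow_minutes,
    nonwear_allow_ceiling = nonwear_allow_ceiling,
    valid_day_minutes = valid_day_minutes,
    min_valid_days = min_valid_days,
    min_weekday_valid = min_weekday_valid,
    min_weekend_valid = min_weekend_valid,
    met_threshold = met_threshold,
    cutpoint_table = cutpoint_table,
    combine = combine,
    split_frac = split_frac,
    stratify_by_season = stratify_by_season,
    coefficient_source = coefficient_source,
    awake_minutes_per_week = awake_minutes_per_week,
    guideline_weekly_minutes = guideline_weekly_minutes,
    output_dir = output_dir
  ), class = "paq_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_paq_config()` returns a [paq_config()]; `write_paq_config()`
#'   returns `path` invisibly.
#' @export
read_paq_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) %in% names(formals(paq_config))]
  if (!is.null(vals$cutpoint_table)) vals$cutpoint_table <- unlist(vals$cutpoint_table)
  do.call(paq_config, vals)
}

#' @rdname read_paq_config
#' @param config A [paq_config()] object.
#' @export
write_paq_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
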