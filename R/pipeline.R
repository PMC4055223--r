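# End-to-end orchestration: simulate a study directory, then screen, score,
# split, fit and validate it, logging every inclusion/exclusion decision.

#' Simulate a study directory
#'
#' Generates a synthetic cohort and writes the three inputs the pipeline
#' consumes: a participant roster (`roster.csv`), one epoch-count CSV per
#' participant under `epochs/`, and a long-format PAQ item file
#' (`paq_items.csv`). The cohort's hidden truth (`truth.csv`: true PAQ and
#' %MVPA) and the generating configuration are stored alongside for
#' inspection; the pipeline itself never reads them.
#'
#' @param config A [paq_config()]; `n_participants`, `seed` and `output_dir`
#'   drive the simulation.
#' @param params Optional [cohort_params()] overriding the defaults derived
#'   from `config`.
#' @return Invisibly, a list of the written paths.
#' @export
run_simulate <- function(config = paq_config(), params = NULL) {
  params <- params %||% cohort_params(n_participants = config$n_participants,
                                      seed = config$seed)
  cohort <- generate_cohort(params)
  dir <- config$output_dir
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)

  roster <- dplyr::select(cohort, "participant_id", "sex", "age", "form",
                          "season", "bmi")
  readr::write_csv(roster, file.path(dir, "roster.csv"))
  readr::write_csv(dplyr::select(cohort, "participant_id", "paq_true",
                                 "pct_mvpa_true"),
                   file.path(dir, "truth.csv"))
  epoch_paths <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
    trace <- generate_epoch_trace(cohort[i, ])
    write_epoch_csv(trace, file.path(dir, "epochs",
                                     paste0(cohort$participant_id[i], ".csv")))
  })
  paq_items <- purrr::map_dfr(seq_len(nrow(cohort)),
                              function(i) generate_paq_items(cohort[i, ]))
  readr::write_csv(paq_items, file.path(dir, "paq_items.csv"))
  write_paq_config(config, file.path(dir, "config.yaml"))
  message(sprintf("Simulated %d participants (seed %d) into %s",
                  nrow(cohort), params$seed, dir))
  invisible(list(dir = dir,
                 roster = file.path(dir, "roster.csv"),
                 paq_items = file.path(dir, "paq_items.csv"),
                 epochs = epoch_paths))
}

#' Run the calibration pipeline on a study directory
#'
#' Reads the roster, epoch files and PAQ items from `config$output_dir`, then
#' runs the five stages: accelerometer screening, PAQ scoring, merge,
#' calibration/validation split, model fit (or the published coefficients if
#' `coefficient_source = "published"`), and hold-out validation with
#' agreement and guideline-classification reports. Every participant is
#' logged exactly once as included or excluded with the triggering rule.
#' Reports are written as CSVs under `config$output_dir/reports`.
#'
#' @param config A [paq_config()].
#' @return An object of class `paq_pipeline`: a list with `screening`,
#'   `paq_scores`, `analysis` (the merged table with split labels), `fit`
#'   (`NULL` when using published coefficients), `coefficients`, `agreement`,
#'   `classification` and `log`.
#' @export
run_pipeline <- function(config = paq_config()) {
  dir <- config$output_dir
  roster <- readr::read_csv(file.path(dir, "roster.csv"), show_col_types = FALSE)
  epoch_files <- list.files(file.path(dir, "epochs"), full.names = TRUE,
                            pattern = "\\.csv$")
  if (!length(epoch_files)) abort(sprintf("No epoch files under %s/epochs.", dir))
  epochs <- purrr::map_dfr(epoch_files, read_epoch_csv)

  screening <- screen_accel(epochs, roster, config)
  paq_scores <- score_paq(read_paq_csv(file.path(dir, "paq_items.csv")))

  persons <- dplyr::filter(screening$persons, .data$week_valid)
  if (!nrow(persons)) abort("No valid weeks after screening; nothing to calibrate.")
  analysis <- roster %>%
    dplyr::inner_join(persons, by = "participant_id") %>%
    dplyr::inner_join(dplyr::select(paq_scores, "participant_id",
                                    paq = "paq_score"),
                      by = "participant_id") %>%
    dplyr::mutate(pct_mvpa = .data$pct_mvpa_combined)

  log <- dplyr::bind_rows(
    screening$exclusions %>% dplyr::mutate(status = "excluded"),
    roster %>%
      dplyr::filter(!.data$participant_id %in% screening$persons$participant_id) %>%
      dplyr::transmute(.data$participant_id, reason = "no epoch data",
                       status = "excluded"),
    roster %>%
      dplyr::filter(.data$participant_id %in% analysis$participant_id) %>%
      dplyr::transmute(.data$participant_id, reason = "passed screening",
                       status = "included")
  )
  no_paq <- setdiff(persons$participant_id, paq_scores$participant_id)
  if (length(no_paq)) {
    log <- dplyr::bind_rows(log, tibble::tibble(participant_id = no_paq,
                                                reason = "no PAQ responses",
                                                status = "excluded"))
  }

  analysis <- split_sample(analysis, frac = config$split_frac, seed = config$seed,
                           stratify_by = if (config$stratify_by_season) "season")
  cal <- dplyr::filter(analysis, .data$split == "calibration")
  val <- dplyr::filter(analysis, .data$split == "validation")

  if (config$coefficient_source == "fit") {
    fit <- fit_calibration(cal)
    co <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  } else {
    fit <- NULL
    co <- paq_reference_coefficients()
  }

  predictions <- make_predictions(val, coefficients = co,
                                  awake_minutes_per_week = config$awake_minutes_per_week)
  agreement <- evaluate_agreement(predictions)
  classification <- guideline_classification(
    predictions, threshold_weekly_minutes = config$guideline_weekly_minutes)

  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  if (!is.null(fit)) {
    readr::write_csv(tidy(fit), file.path(rep_dir, "fit_coefficients.csv"))
    readr::write_csv(glance(fit), file.path(rep_dir, "fit_summary.csv"))
  }
  readr::write_csv(predictions, file.path(rep_dir, "predictions.csv"))
  readr::write_csv(glance(agreement), file.path(rep_dir, "agreement.csv"))
  readr::write_csv(glance(classification), file.path(rep_dir, "classification.csv"))
  readr::write_csv(log, file.path(rep_dir, "participant_log.csv"))
  readr::write_csv(screening$days, file.path(rep_dir, "day_summaries.csv"))
  readr::write_csv(screening$persons, file.path(rep_dir, "person_summaries.csv"))

  structure(list(screening = screening, paq_scores = paq_scores,
                 analysis = analysis, fit = fit, coefficients = co,
                 agreement = agreement, classification = classification,
                 log = log),
            class = "paq_pipeline")
}

#' @export
print.paq_pipeline <- function(x, ...) {
  cat(sprintf("<paq_pipeline> %d analysed (%d calibration / %d validation), %d excluded\n",
              nrow(x$analysis),
              sum(x$analysis$split == "calibration"),
              sum(x$analysis$split == "validation"),
              sum(x$log$status == "excluded")))
  if (!is.null(x$fit)) print(x$fit)
  print(x$agreement)
  print(x$classification)
  invisible(x)
}
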