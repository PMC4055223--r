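#' @importFrom dplyr %>%
NULL

# Scored items besides the activity checklist, by form. The checklist is
# item 1; recess is asked of children (PAQ-C) but not adolescents (PAQ-A).
# A "sick last week" item, if present, is never scored.
paq_items_for_form <- function(form) {
  base <- c("pe", "lunch", "after_school", "evening", "weekend",
            "week_describe", "week_daily")
  switch(form,
         "PAQ-C" = c("pe", "recess", base[-1]),
         "PAQ-A" = base,
         abort(sprintf("Unknown PAQ form \"%s\"; expected \"PAQ-C\" or \"PAQ-A\".", form)))
}

check_responses <- function(x, what) {
  bad <- !is.numeric(x) | is.na(x) | x < 1 | x > 5 | x != round(x)
  if (any(bad)) {
    abort(sprintf("%s responses must be integers in 1..5 (offending value: %s).",
                  what, paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

#' Score the PAQ activity checklist
#'
#' The first PAQ item is a checklist of common sports and games, each rated on
#' the 1--5 frequency scale. Its item score is the plain mean of the activity
#' ratings, kept on the 1--5 scale.
#'
#' @param responses Integer vector of checklist ratings, each in 1..5.
#' @return The checklist item score (a single number in \[1, 5\]).
#' @examples
#' score_checklist(c(1, 3, 5))
#' @export
score_checklist <- function(responses) {
  if (!length(responses)) abort("Checklist must contain at least one activity response.")
  check_responses(responses, "Checklist")
  mean(responses)
}

#' Score a single PAQ response
#'
#' Computes the PAQ summary score: the mean of the checklist item score and the
#' remaining item scores (9 scored items for PAQ-C, 8 for PAQ-A, the recess
#' item being child-form only). Missing required items are an error -- there is
#' no imputation or pro-rating.
#'
#' @param checklist Integer vector of checklist ratings (1..5).
#' @param items Named integer vector of the remaining item responses; names
#'   must cover `pe`, `recess` (PAQ-C only), `lunch`, `after_school`,
#'   `evening`, `weekend`, `week_describe`, `week_daily`. A `sick` entry is
#'   ignored.
#' @param form `"PAQ-C"` or `"PAQ-A"`.
#' @return The summary score, full precision, in \[1, 5\]. Round to one
#'   decimal place (as [score_paq()] reports in `paq_score_1dp`) when the
#'   score enters the calibration equation.
#' @examples
#' score_paq_response(
#'   checklist = c(3, 4),
#'   items = c(pe = 3, recess = 3, lunch = 3, after_school = 3,
#'             evening = 3, weekend = 3, week_describe = 3, week_daily = 4),
#'   form = "PAQ-C"
#' )
#' @export
score_paq_response <- function(checklist, items, form) {
  required <- paq_items_for_form(form)
  items <- items[setdiff(names(items), "sick")]
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    abort(sprintf("Missing required %s item(s): %s.", form,
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(items), required)
  if (length(unknown)) {
    abort(sprintf("Unknown item(s) for %s: %s.", form,
                  paste(unknown, collapse = ", ")))
  }
  check_responses(items, "Item")
  mean(c(score_checklist(checklist), unname(items[required])))
}

#' Score a table of PAQ responses
#'
#' Data-frame-first scorer for long-format PAQ data: one row per participant,
#' item and response. Checklist entries are rows whose `item` starts with
#' `"checklist"`; they are averaged into the single checklist item score
#' before the overall item mean is taken.
#'
#' @param data A data frame with columns `participant_id`, `form` (`"PAQ-C"`
#'   or `"PAQ-A"`), `item`, `response`.
#' @return A tibble with one row per participant: `participant_id`, `form`,
#'   `n_items` (scored items including the checklist), `paq_score` (full
#'   precision) and `paq_score_1dp` (rounded to one decimal place, the form in
#'   which the score enters the calibration equation).
#' @seealso [score_paq_response()], [read_paq_csv()]
#' @export
score_paq <- function(data) {
  assert_columns(data, c("participant_id", "form", "item", "response"), "PAQ data")
  data %>%
    dplyr::group_by(.data$participant_id, .data$form) %>%
    dplyr::group_modify(function(d, key) {
      is_check <- stringr::str_starts(d$item, "checklist")
      checklist <- d$response[is_check]
      if (!length(checklist)) {
        abort(sprintf("Participant %s: no checklist responses.", key$participant_id))
      }
      items <- setNames(d$response[!is_check], d$item[!is_check])
      score <- score_paq_response(checklist, items, key$form)
      n_items <- length(paq_items_for_form(key$form)) + 1L
      tibble::tibble(n_items = n_items,
                     paq_score = score,
                     paq_score_1dp = round(score, 1))
    }) %>%
    dplyr::ungroup()
}

#' Read PAQ item responses from CSV
#'
#' Accepts either long format (columns `participant_id`, `form`, `item`,
#' `response`) or wide format (one row per participant, one column per item,
#' checklist columns named `checklist_1`, `checklist_2`, ...). Wide input is
#' pivoted to long.
#'
#' @param path Path to the CSV file.
#' @return A long-format tibble ready for [score_paq()].
#' @export
read_paq_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(data, c("participant_id", "form"), "PAQ file")
  if (all(c("item", "response") %in% names(data))) {
    return(tibble::as_tibble(data))
  }
  tidyr::pivot_longer(data, -c("participant_id", "form"),
                      names_to = "item", values_to = "response",
                      values_drop_na = TRUE)
}
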