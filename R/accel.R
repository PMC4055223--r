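# Screening of 30-second epoch activity counts: day window restriction,
# minute aggregation, non-wear detection, MVPA classification, and per-day /
# per-week summaries with validity rules.

EPOCH_SECONDS <- 30L

validate_epochs <- function(epochs, what = "epoch data") {
  assert_columns(epochs, c("participant_id", "timestamp", "counts"), what)
  if (!inherits(epochs$timestamp, "POSIXct")) {
    abort(sprintf("%s: `timestamp` must be POSIXct.", what))
  }
  bad <- which(is.na(epochs$counts) | epochs$counts < 0 | epochs$counts != round(epochs$counts))
  if (length(bad)) {
    abort(sprintf("%s: counts must be non-negative integers (first offending row: %d).",
                  what, bad[1]))
  }
  invisible(epochs)
}

#' Read a 30-second epoch activity-count file
#'
#' Parses the per-participant epoch CSV written by [generate_epoch_trace()] /
#' [run_simulate()]: two metadata lines (`participant_id,<id>` and
#' `epoch_seconds,30`), a `timestamp,counts` header, then one row per epoch
#' with an ISO-8601 timestamp and an integer count. With
#' `tolerate_vendor_header = TRUE`, unrecognised lines before the data header
#' (an Actigraph-export-style preamble) are skipped instead of raising an
#' error.
#'
#' Validation is strict: counts must be non-negative integers, timestamps must
#' be strictly increasing with constant 30-second spacing within each day, and
#' the declared epoch length must be 30 s. Errors name the offending file line.
#'
#' @param path Path to the epoch CSV.
#' @param tolerate_vendor_header Skip unrecognised preamble lines.
#' @return A tibble with columns `participant_id`, `timestamp` (POSIXct, UTC),
#'   `counts` (integer).
#' @export
read_epoch_csv <- function(path, tolerate_vendor_header = FALSE) {
  lines <- readr::read_lines(path)
  header_at <- which(lines == "timestamp,counts")[1]
  if (is.na(header_at)) abort(sprintf("%s: no `timestamp,counts` header found.", path))
  meta <- lines[seq_len(header_at - 1L)]
  get_meta <- function(key) {
    hit <- grep(paste0("^", key, ","), meta, value = TRUE)
    if (length(hit) != 1L) return(NA_character_)
    sub(paste0("^", key, ","), "", hit)
  }
  pid <- get_meta("participant_id")
  eps <- suppressWarnings(as.integer(get_meta("epoch_seconds")))
  recognised <- grepl("^(participant_id|epoch_seconds),", meta)
  if (any(!recognised) && !tolerate_vendor_header) {
    abort(sprintf("%s: unrecognised header line %d (set tolerate_vendor_header = TRUE to skip).",
                  path, which(!recognised)[1]))
  }
  if (is.na(pid)) abort(sprintf("%s: missing `participant_id` metadata line.", path))
  if (is.na(eps) || eps != EPOCH_SECONDS) {
    abort(sprintf("%s: epoch length must be %d seconds (declared: %s).",
                  path, EPOCH_SECONDS, get_meta("epoch_seconds")))
  }

  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(body)]
  line_no <- header_at + seq_along(body)
  parts <- stringr::str_split_fixed(body, ",", 2)
  ts <- lubridate::ymd_hms(parts[, 1], tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) {
    abort(sprintf("%s: unparseable timestamp at line %d.", path, line_no[which(is.na(ts))[1]]))
  }
  counts <- suppressWarnings(as.numeric(parts[, 2]))
  bad <- is.na(counts) | counts < 0 | counts != round(counts)
  if (any(bad)) {
    abort(sprintf("%s: counts must be non-negative integers (line %d).",
                  path, line_no[which(bad)[1]]))
  }
  step <- diff(as.numeric(ts))
  same_day <- as.Date(ts[-1]) == as.Date(ts[-length(ts)])
  wrong <- which(same_day & step != EPOCH_SECONDS)
  if (length(wrong)) {
    if (any(step[wrong] <= 0)) {
      abort(sprintf("%s: non-monotone timestamps at line %d.",
                    path, line_no[wrong[which(step[wrong] <= 0)[1]] + 1L]))
    }
    abort(sprintf("%s: epoch spacing is %s s, not %d s, at line %d.",
                  path, format(step[wrong[1]]), EPOCH_SECONDS, line_no[wrong[1] + 1L]))
  }
  tibble::tibble(participant_id = pid, timestamp = ts, counts = as.integer(counts))
}

#' Write a 30-second epoch activity-count file
#'
#' Inverse of [read_epoch_csv()]; one file per participant.
#'
#' @param epochs Epoch tibble (`participant_id`, `timestamp`, `counts`) for a
#'   single participant.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(epochs, path) {
  validate_epochs(epochs)
  pid <- unique(epochs$participant_id)
  if (length(pid) != 1L) abort("write_epoch_csv() expects a single participant.")
  lines <- c(
    paste0("participant_id,", pid),
    paste0("epoch_seconds,", EPOCH_SECONDS),
    "timestamp,counts",
    paste0(format(epochs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), ",", epochs$counts)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Restrict epochs to the monitoring day window
#'
#' Keeps only epochs whose timestamp falls in the half-open daily window
#' `[start, end)` -- by default 8 a.m. to 9 p.m., the 780-minute window used to
#' minimise dilution of activity by misclassified sleep time. An epoch
#' stamped exactly at the window end is excluded.
#'
#' @param epochs Epoch tibble.
#' @param start,end Clock times `"HH:MM"`; `start` must precede `end`.
#' @return The filtered epoch tibble.
#' @export
restrict_day_window <- function(epochs, start = "08:00", end = "21:00") {
  validate_epochs(epochs)
  s <- parse_clock(start, "start")
  e <- parse_clock(end, "end")
  if (s >= e) abort("Day window start must precede end.")
  mod <- lubridate::hour(epochs$timestamp) * 60 + lubridate::minute(epochs$timestamp)
  dplyr::filter(epochs, mod >= s, mod < e)
}

#' Aggregate 30-second epochs to clock-minute counts
#'
#' Sums the pair of epochs aligned to each clock minute into a
#' counts-per-minute (cpm) value, the unit in which the non-wear rule is
#' stated. Clock minutes covered by only one epoch (window edges, truncated
#' recordings) are dropped from the minute series; such epochs still take part
#' in MVPA classification downstream.
#'
#' @param epochs Epoch tibble (typically after [restrict_day_window()]).
#' @return A tibble with columns `participant_id`, `date`, `minute` (POSIXct,
#'   start of the clock minute) and `cpm`.
#' @export
to_minute_counts <- function(epochs) {
  validate_epochs(epochs)
  epochs %>%
    dplyr::mutate(minute = lubridate::floor_date(.data$timestamp, "minute")) %>%
    dplyr::group_by(.data$participant_id, .data$minute) %>%
    dplyr::summarise(cpm = sum(.data$counts), n_epochs = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n_epochs == 2L) %>%
    dplyr::mutate(date = as.Date(.data$minute)) %>%
    dplyr::select("participant_id", "date", "minute", "cpm")
}

# Core non-wear scan for one contiguous minute-level cpm vector.
# A maximal candidate run consists of zero-count minutes, optionally broken by
# interior interruptions of at most `allow_max_minutes` consecutive minutes
# each with cpm in (0, allow_ceiling]; interruptions must be flanked by zeros.
# The run is non-wear iff its total length (zeros + interruptions) reaches
# `min_bout` minutes. Any minute above the ceiling, or an overlong
# interruption, terminates the candidate.
nonwear_mask <- function(cpm, min_bout = 90, allow_max_minutes = 2, allow_ceiling = 100) {
  n <- length(cpm)
  mask <- logical(n)
  if (!n) return(mask)
  cls <- ifelse(cpm == 0, "z", ifelse(cpm <= allow_ceiling, "a", "h"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open_start <- NA_integer_
  open_end <- NA_integer_
  close_candidate <- function() {
    if (!is.na(open_start) && (open_end - open_start + 1L) >= min_bout) {
      mask[open_start:open_end] <<- TRUE
    }
    open_start <<- NA_integer_
    open_end <<- NA_integer_
  }
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    len <- r$lengths[i]
    if (v == "z") {
      if (is.na(open_start)) open_start <- starts[i]
      open_end <- ends[i]
    } else if (v == "a") {
      interior <- !is.na(open_start) &&
        len <= allow_max_minutes &&
        i < length(r$values) && r$values[i + 1L] == "z"
      if (interior) {
        open_end <- ends[i]   # provisional; next run is zeros and extends it
      } else {
        close_candidate()
      }
    } else {
      close_candidate()
    }
  }
  close_candidate()
  mask
}

#' Detect non-wear time in a minute-level count series
#'
#' Flags non-wear as continuous bouts of at least `min_bout` minutes (default
#' 90) at 0 counts per minute, allowing interruptions of up to
#' `allow_max_minutes` consecutive minutes (default 2) with counts per minute
#' in `(0, allow_ceiling]` (default 100). Any minute above the ceiling, or an
#' interruption longer than the allowance, terminates the candidate bout.
#' The scan runs independently within each participant-day and within each
#' contiguous stretch of minutes.
#'
#' @param minutes Minute-level tibble from [to_minute_counts()].
#' @param min_bout Minimum bout length in minutes for non-wear.
#' @param allow_max_minutes Maximum consecutive low-count minutes tolerated
#'   inside a bout.
#' @param allow_ceiling Highest cpm an interruption minute may carry.
#' @return `minutes` with a logical `wear` column (`TRUE` = worn).
#' @export
detect_nonwear <- function(minutes, min_bout = 90, allow_max_minutes = 2,
                           allow_ceiling = 100) {
  assert_columns(minutes, c("participant_id", "date", "minute", "cpm"), "minute data")
  assert_number(min_bout, "min_bout", lower = 1)
  assert_number(allow_max_minutes, "allow_max_minutes", lower = 0)
  assert_number(allow_ceiling, "allow_ceiling", lower = 0)
  if (!nrow(minutes)) return(dplyr::mutate(minutes, wear = logical(0)))
  minutes %>%
    dplyr::arrange(.data$participant_id, .data$minute) %>%
    dplyr::group_by(.data$participant_id, .data$date) %>%
    dplyr::group_modify(function(d, key) {
      # split at gaps so bouts never span missing minutes
      gap <- c(0, diff(as.numeric(d$minute)) != 60)
      seg <- cumsum(gap)
      d$wear <- !unlist(lapply(split(d$cpm, seg), nonwear_mask,
                               min_bout = min_bout,
                               allow_max_minutes = allow_max_minutes,
                               allow_ceiling = allow_ceiling),
                        use.names = FALSE)
      d
    }) %>%
    dplyr::ungroup()
}

# Freedson-style age-based MET prediction from counts per minute:
# METs = 2.757 + 0.0015 cpm - 0.08957 age - 0.000038 cpm * age
freedson_age_coefficients <- function() {
  c(intercept = 2.757, cpm = 0.0015, age = -0.08957, cpm_age = -0.000038)
}

#' Age-specific MVPA cut point in counts per minute
#'
#' Inverts an age-based MET prediction equation at the MVPA intensity floor
#' (default 4 METs) to obtain the counts-per-minute threshold for each age.
#' The default equation is the Freedson age model
#' `METs = 2.757 + 0.0015 cpm - 0.08957 age - 0.000038 cpm x age`, so the
#' threshold is `(met_threshold - intercept - age_coef x age) / (cpm_coef +
#' cpm_age_coef x age)`, rounded to the nearest whole count. Halve the result
#' for the per-30-second-epoch threshold (see [epoch_threshold()]). A
#' user-supplied `cutpoint_table` (named vector, age to cpm) overrides the
#' equation and is returned verbatim.
#'
#' @param age_years Integer age(s), 8--14.
#' @param met_threshold MVPA intensity floor in METs (> 1).
#' @param met_coefficients Named vector `intercept`, `cpm`, `age`, `cpm_age`.
#' @param cutpoint_table Optional named numeric vector mapping age to cpm.
#' @param round_threshold Round the derived cpm to the nearest integer count.
#' @return Counts-per-minute threshold(s), one per input age.
#' @examples
#' mvpa_cutpoint_cpm(10)  # ~1910 cpm
#' @export
mvpa_cutpoint_cpm <- function(age_years, met_threshold = 4,
                              met_coefficients = freedson_age_coefficients(),
                              cutpoint_table = NULL,
                              round_threshold = TRUE) {
  if (any(age_years < 8 | age_years > 14)) {
    warn("Ages outside 8-14 are outside the calibrated range for the cut-point equation.")
  }
  if (!is.null(cutpoint_table)) {
    hit <- cutpoint_table[as.character(age_years)]
    if (anyNA(hit)) abort("cutpoint_table has no entry for one of the requested ages.")
    return(unname(hit))
  }
  assert_number(met_threshold, "met_threshold", lower = 1)
  b <- met_coefficients
  denom <- b[["cpm"]] + b[["cpm_age"]] * age_years
  if (any(abs(denom) < 1e-12)) {
    abort("Degenerate cut-point equation: cpm coefficient vanishes at this age.")
  }
  cpm <- (met_threshold - b[["intercept"]] - b[["age"]] * age_years) / denom
  if (any(cpm < 0)) abort("Cut-point equation yields a negative cpm threshold.")
  if (round_threshold) cpm <- round(cpm)
  unname(cpm)
}

#' Per-epoch threshold from a counts-per-minute cut point
#'
#' @param cpm Counts-per-minute threshold(s).
#' @return The scaled per-30-second-epoch threshold (`cpm / 2`).
#' @export
epoch_threshold <- function(cpm) cpm / 2

#' Classify epochs as MVPA
#'
#' An epoch counts as MVPA iff its counts reach the per-epoch threshold
#' *and* its clock minute is wear time. Minutes absent from the wear mask
#' (unpaired edge epochs dropped by [to_minute_counts()]) are treated as worn.
#' MVPA minutes are MVPA epochs / 2.
#'
#' @param epochs Epoch tibble (after [restrict_day_window()]).
#' @param wear_minutes Output of [detect_nonwear()].
#' @param epoch_threshold Either a single per-epoch count threshold or a data
#'   frame with columns `participant_id`, `epoch_threshold` for age-specific
#'   thresholds.
#' @return `epochs` with logical columns `wear` and `mvpa`.
#' @export
classify_mvpa <- function(epochs, wear_minutes, epoch_threshold) {
  validate_epochs(epochs)
  out <- epochs %>%
    dplyr::mutate(minute = lubridate::floor_date(.data$timestamp, "minute")) %>%
    dplyr::left_join(dplyr::select(wear_minutes, "participant_id", "minute", "wear"),
                     by = c("participant_id", "minute")) %>%
    dplyr::mutate(wear = dplyr::coalesce(.data$wear, TRUE))
  if (is.data.frame(epoch_threshold)) {
    assert_columns(epoch_threshold, c("participant_id", "epoch_threshold"), "threshold table")
    out <- dplyr::left_join(out, epoch_threshold, by = "participant_id")
    if (anyNA(out$epoch_threshold)) abort("No epoch threshold for some participant(s).")
  } else {
    assert_number(epoch_threshold, "epoch_threshold", lower = 0)
    out$epoch_threshold <- epoch_threshold
  }
  out %>%
    dplyr::mutate(mvpa = .data$wear & .data$counts >= .data$epoch_threshold) %>%
    dplyr::select(-"minute", -"epoch_threshold")
}

#' Summarise one screened day per participant
#'
#' Computes wear minutes, MVPA minutes, percent of wear time in MVPA, mean
#' counts per wear minute, the weekend flag, and day validity. A day is valid
#' when wear time reaches `valid_day_minutes` (default 546 = 70% of the
#' 780-minute window, inclusive). `pct_mvpa` is undefined (NA) for days with
#' no wear.
#'
#' @param classified Epoch tibble from [classify_mvpa()].
#' @param valid_day_minutes Minimum wear minutes for a valid day.
#' @return A tibble with one row per participant-day: `participant_id`,
#'   `date`, `is_weekend`, `wear_minutes`, `mvpa_minutes`, `pct_mvpa`,
#'   `cpm_mean`, `valid`.
#' @export
summarize_day <- function(classified, valid_day_minutes = 546) {
  assert_columns(classified, c("participant_id", "timestamp", "counts", "wear", "mvpa"),
                 "classified epochs")
  classified %>%
    dplyr::mutate(date = as.Date(.data$timestamp)) %>%
    dplyr::group_by(.data$participant_id, .data$date) %>%
    dplyr::summarise(
      wear_minutes = sum(.data$wear) / 2,
      mvpa_minutes = sum(.data$mvpa) / 2,
      cpm_mean = ifelse(sum(.data$wear) > 0,
                        sum(.data$counts[.data$wear]) / (sum(.data$wear) / 2),
                        NA_real_),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      is_weekend = lubridate::wday(.data$date, week_start = 1) >= 6,
      pct_mvpa = ifelse(.data$wear_minutes > 0,
                        100 * .data$mvpa_minutes / .data$wear_minutes, NA_real_),
      valid = .data$wear_minutes >= valid_day_minutes
    ) %>%
    dplyr::select("participant_id", "date", "is_weekend", "wear_minutes",
                  "mvpa_minutes", "pct_mvpa", "cpm_mean", "valid")
}

#' Summarise a participant-week of screened days
#'
#' Aggregates per-day summaries into the weekly outcomes used for
#' calibration. Weekday and weekend %MVPA are means of per-valid-day
#' `pct_mvpa` within each stratum. The combined outcome defaults to the
#' calendar-weighted mean `(5 x weekday + 2 x weekend) / 7`
#' (`combine = "weighted"`); `combine = "unweighted"` averages over all valid
#' days instead. A week is valid with at least `min_valid_days` valid days of
#' which at least `min_weekday_valid` weekdays and `min_weekend_valid` weekend
#' days (default 4 / 3 / 1); invalid weeks carry `NA` combined %MVPA.
#'
#' @param days Day summaries from [summarize_day()].
#' @param combine `"weighted"` or `"unweighted"`.
#' @param min_valid_days,min_weekday_valid,min_weekend_valid Week validity
#'   thresholds.
#' @return A tibble with one row per participant: valid-day counts, stratum
#'   and combined %MVPA, daily means of MVPA minutes, wear minutes and cpm
#'   (over valid days), and `week_valid`.
#' @export
summarize_week <- function(days, combine = c("weighted", "unweighted"),
                           min_valid_days = 4, min_weekday_valid = 3,
                           min_weekend_valid = 1) {
  combine <- match.arg(combine)
  assert_columns(days, c("participant_id", "is_weekend", "pct_mvpa",
                         "mvpa_minutes", "wear_minutes", "cpm_mean", "valid"),
                 "day summaries")
  days %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(
      valid_days = sum(.data$valid),
      weekday_valid = sum(.data$valid & !.data$is_weekend),
      weekend_valid = sum(.data$valid & .data$is_weekend),
      pct_mvpa_weekday = mean(.data$pct_mvpa[.data$valid & !.data$is_weekend]),
      pct_mvpa_weekend = mean(.data$pct_mvpa[.data$valid & .data$is_weekend]),
      pct_mvpa_all_valid = mean(.data$pct_mvpa[.data$valid]),
      mvpa_min_daily_mean = mean(.data$mvpa_minutes[.data$valid]),
      wear_minutes_daily_mean = mean(.data$wear_minutes[.data$valid]),
      cpm_daily_mean = mean(.data$cpm_mean[.data$valid]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      week_valid = .data$valid_days >= min_valid_days &
        .data$weekday_valid >= min_weekday_valid &
        .data$weekend_valid >= min_weekend_valid,
      pct_mvpa_combined = dplyr::case_when(
        !.data$week_valid ~ NA_real_,
        combine == "weighted" ~ (5 * .data$pct_mvpa_weekday + 2 * .data$pct_mvpa_weekend) / 7,
        TRUE ~ .data$pct_mvpa_all_valid
      )
    ) %>%
    dplyr::select("participant_id", "valid_days", "weekday_valid", "weekend_valid",
                  "pct_mvpa_weekday", "pct_mvpa_weekend", "pct_mvpa_combined",
                  "mvpa_min_daily_mean", "wear_minutes_daily_mean",
                  "cpm_daily_mean", "week_valid")
}

#' Screen epoch data end to end
#'
#' Runs the full screening chain -- day-window restriction, minute
#' aggregation, non-wear detection, age-specific MVPA classification, per-day
#' and per-week summaries -- for a whole cohort, and records why each excluded
#' participant failed the week-validity rule.
#'
#' @param epochs Epoch tibble for one or more participants.
#' @param roster Tibble with `participant_id`, `age` (years); used for the
#'   age-specific cut points.
#' @param config A [paq_config()] list controlling windows, non-wear rules and
#'   validity thresholds.
#' @return An object of class `paq_screening`: a list with tibbles `days`,
#'   `persons` and `exclusions` (participant and reason).
#' @export
screen_accel <- function(epochs, roster, config = paq_config()) {
  assert_columns(roster, c("participant_id", "age"), "roster")
  windowed <- restrict_day_window(epochs, config$window_start, config$window_end)
  minutes <- to_minute_counts(windowed)
  minutes <- detect_nonwear(minutes,
                            min_bout = config$nonwear_min_bout,
                            allow_max_minutes = config$nonwear_allow_minutes,
                            allow_ceiling = config$nonwear_allow_ceiling)
  thresholds <- roster %>%
    dplyr::distinct(.data$participant_id, .data$age) %>%
    dplyr::mutate(epoch_threshold = epoch_threshold(
      mvpa_cutpoint_cpm(.data$age, met_threshold = config$met_threshold,
                        cutpoint_table = config$cutpoint_table))) %>%
    dplyr::select("participant_id", "epoch_threshold")
  classified <- classify_mvpa(windowed, minutes, thresholds)
  days <- summarize_day(classified, valid_day_minutes = config$valid_day_minutes)
  persons <- summarize_week(days, combine = config$combine,
                            min_valid_days = config$min_valid_days,
                            min_weekday_valid = config$min_weekday_valid,
                            min_weekend_valid = config$min_weekend_valid)
  exclusions <- persons %>%
    dplyr::filter(!.data$week_valid) %>%
    dplyr::transmute(
      .data$participant_id,
      reason = sprintf(
        "invalid week: %d valid days (%d weekday, %d weekend); need >=%d total, >=%d weekday, >=%d weekend",
        .data$valid_days, .data$weekday_valid, .data$weekend_valid,
        config$min_valid_days, config$min_weekday_valid, config$min_weekend_valid))
  structure(list(days = days, persons = persons, exclusions = exclusions),
            class = "paq_screening")
}

#' @export
print.paq_screening <- function(x, ...) {
  cat(sprintf("<paq_screening> %d participants, %d days; %d excluded by week validity\n",
              nrow(x$persons), nrow(x$days), nrow(x$exclusions)))
  invisible(x)
}

#' @rdname screen_accel
#' @param x A `paq_screening` object.
#' @param ... Unused.
#' @method tidy paq_screening
#' @export
tidy.paq_screening <- function(x, ...) x$persons
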