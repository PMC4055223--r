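# Synthetic cohorts, epoch-count traces and PAQ item responses with the
# statistical structure the calibration analysis assumes.

# Monday anchors for the two data-collection seasons of a school year.
season_anchor <- function(season) {
  switch(season,
         fall = as.Date("2009-10-05"),
         spring = as.Date("2010-04-12"),
         abort(sprintf("Unknown season \"%s\".", season)))
}

#' Parameters for a synthetic calibration cohort
#'
#' Bundles the generating distribution of a simulated cohort of 8--14 year
#' olds. Defaults reproduce the structure of the published calibration
#' sample: PAQ summary scores around 3.2 (SD 0.7) for children up to 11 and
#' 2.8 for adolescents, roughly half boys, a slight spring excess, and true
#' percent time in MVPA generated from the published equation
#' `14.56 - 0.98 sex - 0.84 age + 1.01 PAQ` plus Gaussian noise with SD equal
#' to the published residual error of 2.54 percentage points, floored at 0.
#'
#' @param n_participants Cohort size.
#' @param age_range Inclusive integer age range, within 8--14.
#' @param age_weights Optional sampling weights over `age_range` (default
#'   uniform).
#' @param prop_male Fraction of boys.
#' @param prop_spring Fraction measured in spring.
#' @param paq_mean_by_age Named vector of PAQ means per age (1--5 scale).
#' @param paq_sd SD of the true PAQ score (truncated to \[1, 5\]).
#' @param residual_sd_pct Residual SD of true %MVPA about the equation, in
#'   percentage points.
#' @param coefficients Named generating coefficients (`intercept`, `sex`,
#'   `age`, `paq`).
#' @param day_sd_pct Between-day SD of a participant's daily %MVPA target
#'   about their weekly value (default 0: every day shares the weekly value).
#' @param nonwear_daily_prob Probability a day contains one non-wear block.
#' @param nonwear_minutes Length range (minutes) of a non-wear block; the
#'   lower bound should reach the 90-minute detection rule.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A classed parameter list (`cohort_params`).
#' @export
cohort_params <- function(n_participants = 148,
                          age_range = c(8L, 14L),
                          age_weights = NULL,
                          prop_male = 0.51,
                          prop_spring = 0.55,
                          paq_mean_by_age = c(`8` = 3.2, `9` = 3.2, `10` = 3.2,
                                              `11` = 3.2, `12` = 2.8, `13` = 2.8,
                                              `14` = 2.8),
                          paq_sd = 0.7,
                          residual_sd_pct = 2.54,
                          coefficients = paq_reference_coefficients(),
                          day_sd_pct = 0,
                          nonwear_daily_prob = 0.2,
                          nonwear_minutes = c(90, 150),
                          seed = 2009L) {
  assert_count(n_participants, "n_participants", lower = 0)
  if (length(age_range) != 2L || age_range[1] < 8 || age_range[2] > 14 ||
      age_range[1] > age_range[2]) {
    abort("`age_range` must be an increasing pair within [8, 14].")
  }
  assert_fraction(prop_male, "prop_male")
  assert_fraction(prop_spring, "prop_spring")
  assert_number(paq_sd, "paq_sd", lower = 1e-9)
  assert_number(residual_sd_pct, "residual_sd_pct", lower = 1e-9)
  assert_number(day_sd_pct, "day_sd_pct", lower = 0)
  assert_fraction(nonwear_daily_prob, "nonwear_daily_prob")
  ages <- as.character(seq(age_range[1], age_range[2]))
  if (!all(ages %in% names(paq_mean_by_age))) {
    abort("`paq_mean_by_age` must name every age in `age_range`.")
  }
  stopifnot(all(c("intercept", "sex", "age", "paq") %in% names(coefficients)))
  structure(list(n_participants = n_participants, age_range = age_range,
                 age_weights = age_weights, prop_male = prop_male,
                 prop_spring = prop_spring, paq_mean_by_age = paq_mean_by_age,
                 paq_sd = paq_sd, residual_sd_pct = residual_sd_pct,
                 coefficients = coefficients, day_sd_pct = day_sd_pct,
                 nonwear_daily_prob = nonwear_daily_prob,
                 nonwear_minutes = nonwear_minutes,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Evaluate the linear %MVPA equation (no floor).
equation_pct_mvpa <- function(coefficients, sex, age, paq) {
  coefficients[["intercept"]] + coefficients[["sex"]] * sex +
    coefficients[["age"]] * age + coefficients[["paq"]] * paq
}

# Split a target MVPA duration (minutes, multiple of 0.5) into contiguous
# bouts of 2-10 minutes (a single shorter bout if the target is under 2).
bout_lengths <- function(total) {
  if (total <= 0) return(numeric(0))
  if (total <= 10) return(total)
  lens <- c()
  rem <- total
  while (rem > 10) {
    lens <- c(lens, 8)
    rem <- rem - 8
  }
  c(lens, rem)
}

# Place bouts uniformly at random (epoch-aligned) inside [0, seg_len) wear
# segments described by a two-column matrix (start, length in minutes).
place_bouts <- function(segments, lens) {
  if (!length(lens)) return(list(start = numeric(0), len = numeric(0)))
  # capacity-aware assignment: largest bouts first, segment drawn with
  # probability proportional to remaining free time among those that fit
  seg_free <- segments[, 2]
  lens <- sort(lens, decreasing = TRUE)
  seg_pick <- integer(length(lens))
  for (i in seq_along(lens)) {
    fits <- which(seg_free >= lens[i])
    if (!length(fits)) abort("Scheduled MVPA exceeds scheduled wear time.")
    seg_pick[i] <- if (length(fits) == 1L) fits else
      sample(fits, 1L, prob = seg_free[fits])
    seg_free[seg_pick[i]] <- seg_free[seg_pick[i]] - lens[i]
  }
  start_all <- len_all <- numeric(0)
  for (s in seq_len(nrow(segments))) {
    l <- lens[seg_pick == s]
    if (!length(l)) next
    free <- segments[s, 2] - sum(l)
    gaps <- diff(c(0, sort(round(runif(length(l), 0, free) * 2) / 2)))
    starts <- segments[s, 1] + cumsum(gaps) + c(0, cumsum(l[-length(l)]))
    start_all <- c(start_all, starts)
    len_all <- c(len_all, l)
  }
  ord <- order(start_all)
  list(start = start_all[ord], len = len_all[ord])
}

# Build one participant's 7-day schedule: per-day non-wear block, daily %MVPA
# target and MVPA bout placements (minute offsets from the 08:00 window start
# over a 780-minute window).
build_schedule <- function(pct_true, season, params) {
  anchor <- season_anchor(season)
  nw_start <- nw_len <- target <- rep(NA_real_, 7)
  bouts <- vector("list", 7)
  for (day in 1:7) {
    has_nw <- runif(1) < params$nonwear_daily_prob
    if (has_nw) {
      nw_len[day] <- round(runif(1, params$nonwear_minutes[1],
                                 params$nonwear_minutes[2]))
      nw_start[day] <- round(runif(1, 0, 780 - nw_len[day]))
    }
    target[day] <- max(0, pct_true + if (params$day_sd_pct > 0)
      rnorm(1, 0, params$day_sd_pct) else 0)
    wear <- 780 - ifelse(has_nw, nw_len[day], 0)
    target_mvpa <- round(target[day] / 100 * wear * 2) / 2
    segments <- if (has_nw) {
      rbind(c(0, nw_start[day]),
            c(nw_start[day] + nw_len[day], 780 - nw_start[day] - nw_len[day]))
    } else {
      matrix(c(0, 780), nrow = 1)
    }
    segments <- segments[segments[, 2] > 0, , drop = FALSE]
    bouts[[day]] <- place_bouts(segments, bout_lengths(target_mvpa))
  }
  tibble::tibble(day = 1:7, date = anchor + 0:6,
                 nonwear_start = nw_start, nonwear_len = nw_len,
                 target_pct = target, bouts = bouts)
}

#' Generate a synthetic calibration cohort
#'
#' Draws participants with sex, integer age, season, true PAQ score (normal
#' truncated to \[1, 5\] with age-specific means) and true weekly percent time
#' in MVPA from the generating equation plus Gaussian residual noise, floored
#' at 0. Each participant also receives a 7-day wear/MVPA schedule (non-wear
#' blocks and bout placements) and a private trace seed, so epoch traces and
#' PAQ items can be generated reproducibly downstream.
#'
#' @param params A [cohort_params()] list.
#' @return A tibble with one row per participant: `participant_id`, `sex`
#'   (1 = male, 2 = female), `age`, `form` (PAQ-C up to age 11, PAQ-A from
#'   12), `season`, `paq_true`, `pct_mvpa_true`, `trace_seed` and a `schedule`
#'   list-column.
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) abort("`params` must come from cohort_params().")
  n <- params$n_participants
  if (n < 2) abort("Need at least 2 participants (the sample must be splittable).")
  with_seed(params$seed, {
    ages_avail <- seq(params$age_range[1], params$age_range[2])
    age <- sample(ages_avail, n, replace = TRUE, prob = params$age_weights)
    sex <- ifelse(runif(n) < params$prop_male, 1L, 2L)
    season <- ifelse(runif(n) < params$prop_spring, "spring", "fall")
    paq_true <- rtruncnorm(n, params$paq_mean_by_age[as.character(age)],
                           params$paq_sd, 1, 5)
    eps <- rnorm(n, 0, params$residual_sd_pct)
    pct_true <- pmax(0, equation_pct_mvpa(params$coefficients, sex, age, paq_true) + eps)
    trace_seed <- sample.int(2147483646L, n)
    # plain BMI (kg/m^2) carried as a roster field; rises ~1 unit per year
    bmi <- pmax(12, 9 + 1.0 * age + rnorm(n, 0, 3))
    cohort <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      sex = sex, age = age,
      form = ifelse(age <= 11, "PAQ-C", "PAQ-A"),
      season = season,
      bmi = round(bmi, 1),
      paq_true = paq_true,
      pct_mvpa_true = pct_true,
      trace_seed = trace_seed
    )
    cohort$schedule <- purrr::map2(pct_true, season, build_schedule, params = params)
    cohort
  })
}

#' Generate a 7-day 30-second epoch-count trace
#'
#' Renders one participant's schedule into a full week of 30-second epochs
#' (midnight to midnight). Scheduled non-wear blocks are all-zero runs;
#' scheduled MVPA bouts get per-minute counts strictly above the cut point
#' (each epoch at or above the half-cut-point epoch threshold); remaining
#' in-window wear minutes get light counts in `(100, cutpoint_cpm)` so they
#' neither trigger the non-wear allowance nor reach MVPA; time outside the
#' 8 a.m.--9 p.m. window is zero (sleep). The realized fraction of wear time
#' above the cut point matches the scheduled daily target to within one epoch
#' per bout.
#'
#' @param profile One row of a [generate_cohort()] tibble.
#' @param cutpoint_cpm Counts-per-minute MVPA cut point; default derived from
#'   the participant's age via [mvpa_cutpoint_cpm()].
#' @return An epoch tibble (`participant_id`, `timestamp`, `counts`).
#' @export
generate_epoch_trace <- function(profile, cutpoint_cpm = NULL) {
  stopifnot(nrow(profile) == 1L)
  schedule <- profile$schedule[[1]]
  if (!nrow(schedule)) abort("Profile has no scheduled days.")
  if (is.null(cutpoint_cpm)) cutpoint_cpm <- mvpa_cutpoint_cpm(profile$age)
  assert_number(cutpoint_cpm, "cutpoint_cpm", lower = 1)
  ethr <- ceiling(cutpoint_cpm / 2)
  window_start_min <- 8L * 60L

  with_seed(profile$trace_seed, {
    days <- purrr::map(seq_len(nrow(schedule)), function(i) {
      d <- schedule[i, ]
      wear <- 780 - ifelse(is.na(d$nonwear_len), 0, d$nonwear_len)
      b <- d$bouts[[1]]
      if (sum(b$len) > wear) {
        abort("Scheduled MVPA exceeds scheduled wear time.")
      }
      counts <- integer(2880)  # full day of 30-s epochs, all zero
      win_epoch0 <- window_start_min * 2L  # epoch index of 08:00 (0-based)
      # light activity across the window
      n_win <- 780L * 2L
      # keep both epochs of a light minute strictly below the epoch threshold
      light_min <- sample(101:(cutpoint_cpm - 2), 780L, replace = TRUE)
      light <- as.integer(rbind(floor(light_min / 2), ceiling(light_min / 2)))
      counts[win_epoch0 + seq_len(n_win)] <- light
      # non-wear block: zeros
      if (!is.na(d$nonwear_start)) {
        idx <- win_epoch0 + d$nonwear_start * 2L + seq_len(d$nonwear_len * 2L)
        counts[idx] <- 0L
      }
      # MVPA bouts: every epoch at/above the epoch threshold
      for (j in seq_along(b$start)) {
        idx <- win_epoch0 + b$start[j] * 2L + seq_len(b$len[j] * 2L)
        counts[idx] <- ethr + sample(25:1500, length(idx), replace = TRUE)
      }
      counts
    })
    ts0 <- lubridate::as_datetime(schedule$date[1], tz = "UTC")
    n_total <- 2880L * nrow(schedule)
    tibble::tibble(
      participant_id = profile$participant_id,
      timestamp = ts0 + seq(0, by = 30, length.out = n_total),
      counts = unlist(days)
    )
  })
}

#' Generate PAQ item responses for a synthetic participant
#'
#' Produces integer 1--5 item responses (a checklist block plus the scored
#' items for the participant's form) whose mean approximates the true PAQ
#' score. Noise is scaled by the distance of the true score to the 1/5
#' boundaries, so a participant at either extreme answers every item at the
#' extreme regardless of the noise level.
#'
#' @param profile One row of a [generate_cohort()] tibble.
#' @param n_checklist Number of checklist activities.
#' @param item_noise_sd SD of the per-item perturbation (score units).
#' @param seed Optional seed; defaults to the profile's trace seed + 1.
#' @return A long-format response tibble ready for [score_paq()].
#' @export
generate_paq_items <- function(profile, n_checklist = 10, item_noise_sd = 0.3,
                               seed = NULL) {
  stopifnot(nrow(profile) == 1L)
  assert_count(n_checklist, "n_checklist", lower = 1)
  assert_number(item_noise_sd, "item_noise_sd", lower = 0)
  seed <- seed %||% ((profile$trace_seed + 1L) %% 2147483647L)
  items <- paq_items_for_form(profile$form)
  n_total <- n_checklist + length(items)
  with_seed(seed, {
    scale <- max(0, min(1, 5 - profile$paq_true, profile$paq_true - 1))
    latent <- profile$paq_true + rnorm(n_total, 0, item_noise_sd) * scale
    resp <- pmin(5L, pmax(1L, as.integer(round(latent))))
    tibble::tibble(
      participant_id = profile$participant_id,
      form = profile$form,
      item = c(paste0("checklist_", seq_len(n_checklist)), items),
      response = resp
    )
  })
}

#' Construct a minute-level non-wear allowance fixture
#'
#' A deterministic one-day minute series for exercising the non-wear
#' allowance rule: high-count flanks, a zero run, a low-count interruption,
#' and a second zero run.
#'
#' @param zeros_before,zeros_after Zero-minute run lengths around the
#'   interruption.
#' @param interrupt_minutes,interrupt_cpm Interruption length and cpm.
#' @param flank_minutes,flank_cpm High-count flank length and cpm.
#' @return A minute-level tibble for [detect_nonwear()].
#' @export
make_interruption_trace <- function(zeros_before = 50, zeros_after = 48,
                                    interrupt_minutes = 2, interrupt_cpm = 50,
                                    flank_minutes = 5, flank_cpm = 500) {
  cpm <- c(rep(flank_cpm, flank_minutes),
           rep(0, zeros_before),
           rep(interrupt_cpm, interrupt_minutes),
           rep(0, zeros_after),
           rep(flank_cpm, flank_minutes))
  start <- lubridate::ymd_hms("2009-10-05 08:00:00", tz = "UTC")
  tibble::tibble(participant_id = "FIX",
                 date = as.Date(start),
                 minute = start + 60 * (seq_along(cpm) - 1),
                 cpm = cpm)
}
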