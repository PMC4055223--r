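# Hold-out validation: applying a calibration equation, converting percent
# MVPA to weekly minutes, and agreement / guideline-classification statistics.

#' Predict percent time in MVPA from the calibration equation
#'
#' Evaluates the linear calibration equation (default: the published
#' coefficients, see [paq_reference_coefficients()]) for vectors of sex
#' codes, ages and PAQ scores. PAQ scores are rounded to one decimal place
#' before entering the equation; negative predictions are floored at 0.
#'
#' @param sex 1 = male, 2 = female.
#' @param age Age in whole years; values outside 8--14 are allowed with a
#'   warning (outside the calibrated range).
#' @param paq PAQ summary score (1--5).
#' @param coefficients Named vector `intercept`, `sex`, `age`, `paq`.
#' @return Predicted daily %MVPA (percent of wear time), floored at 0.
#' @examples
#' predict_pct_mvpa(1, 9, 3.0)  # 9.05
#' @export
predict_pct_mvpa <- function(sex, age, paq,
                             coefficients = paq_reference_coefficients()) {
  if (!all(sex %in% c(1, 2))) abort("`sex` must be coded 1 (male) or 2 (female).")
  if (any(age < 8 | age > 14)) {
    warn("Ages outside 8-14 are outside the calibrated range of the equation.")
  }
  paq <- round(paq, 1)
  pmax(0, coefficients[["intercept"]] + coefficients[["sex"]] * sex +
         coefficients[["age"]] * age + coefficients[["paq"]] * paq)
}

#' Convert percent MVPA to weekly MVPA minutes
#'
#' Multiplies a daily %MVPA value by the weekly awake-time base (default
#' 5,460 minutes: 13 available hours x 7 days).
#'
#' @param pct Percent of wear time in MVPA.
#' @param awake_minutes_per_week Weekly awake minutes.
#' @return Weekly MVPA minutes.
#' @examples
#' pct_to_weekly_minutes(1.01)  # 55.1 min/week per PAQ unit
#' @export
pct_to_weekly_minutes <- function(pct, awake_minutes_per_week = 5460) {
  assert_number(awake_minutes_per_week, "awake_minutes_per_week", lower = 1)
  pct / 100 * awake_minutes_per_week
}

#' Observed weekly MVPA minutes from accelerometer summaries
#'
#' Puts the accelerometer outcome on the weekly-minutes scale. The default
#' (`mode = "percent"`) converts the combined %MVPA through the same
#' 5,460-minute base as the predictions, so both instruments share a time
#' base; `mode = "minutes"` multiplies the mean daily MVPA minutes by 7
#' instead. The two agree exactly when wear time fills the whole window.
#'
#' @param persons Person summaries from [summarize_week()].
#' @param mode `"percent"` or `"minutes"`.
#' @param awake_minutes_per_week Weekly awake minutes.
#' @return Numeric vector of weekly MVPA minutes, one per row of `persons`.
#' @export
observed_weekly_minutes <- function(persons, mode = c("percent", "minutes"),
                                    awake_minutes_per_week = 5460) {
  mode <- match.arg(mode)
  if (mode == "percent") {
    assert_columns(persons, "pct_mvpa_combined", "person summaries")
    pct_to_weekly_minutes(persons$pct_mvpa_combined, awake_minutes_per_week)
  } else {
    assert_columns(persons, "mvpa_min_daily_mean", "person summaries")
    persons$mvpa_min_daily_mean * 7
  }
}

#' Bland-Altman agreement statistics for paired differences
#'
#' Computes the mean bias, its t-based 95% confidence interval, the 1.96-SD
#' limits of agreement, and the paired t test, from a vector of
#' predicted-minus-observed differences. The SD uses the n - 1 denominator;
#' the limits of agreement use the conventional 1.96 normal multiplier while
#' the CI of the mean bias uses the t quantile.
#'
#' @param differences Numeric vector (predicted - observed), length >= 3.
#' @return An object of class `paq_agreement`; see [glance()] for the one-row
#'   summary.
#' @examples
#' # a sample with mean 25.3 and SD 121.2 reproduces LOA (-212.3, 262.9)
#' @export
bland_altman <- function(differences) {
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 3) abort("Bland-Altman statistics need at least 3 paired differences.")
  mean_bias <- mean(differences)
  sd_diff <- sd(differences)
  se_bias <- sd_diff / sqrt(n)
  tcrit <- qt(0.975, n - 1)
  paired_t <- if (se_bias > 0) mean_bias / se_bias else NaN
  structure(list(
    n = n,
    mean_bias = mean_bias,
    sd_diff = sd_diff,
    se_bias = se_bias,
    ci95 = c(lower = mean_bias - tcrit * se_bias,
             upper = mean_bias + tcrit * se_bias),
    loa = c(lower = mean_bias - 1.96 * sd_diff,
            upper = mean_bias + 1.96 * sd_diff),
    paired_t = paired_t,
    paired_df = n - 1,
    paired_p = if (is.nan(paired_t)) NaN else 2 * pt(-abs(paired_t), n - 1)
  ), class = "paq_agreement")
}

#' Build per-participant prediction records for a validation set
#'
#' Applies a calibration equation to each participant and pairs the result
#' with the accelerometer outcome, both on the weekly-minutes scale.
#'
#' @param data Validation table with columns `participant_id`, `sex`, `age`,
#'   `paq` and the accelerometer outcome (`pct_mvpa_combined` and/or
#'   `mvpa_min_daily_mean`).
#' @param coefficients Calibration coefficients (named vector).
#' @param awake_minutes_per_week Weekly awake minutes.
#' @param observed_mode Passed to [observed_weekly_minutes()].
#' @return A tibble with `participant_id`, `predicted_pct_mvpa`,
#'   `predicted_weekly_minutes`, `observed_weekly_minutes`, `difference`
#'   (predicted - observed).
#' @export
make_predictions <- function(data, coefficients = paq_reference_coefficients(),
                             awake_minutes_per_week = 5460,
                             observed_mode = "percent") {
  assert_columns(data, c("participant_id", "sex", "age", "paq"), "validation data")
  pct <- predict_pct_mvpa(data$sex, data$age, data$paq, coefficients)
  tibble::tibble(
    participant_id = data$participant_id,
    predicted_pct_mvpa = pct,
    predicted_weekly_minutes = pct_to_weekly_minutes(pct, awake_minutes_per_week),
    observed_weekly_minutes = observed_weekly_minutes(data, observed_mode,
                                                      awake_minutes_per_week),
  ) %>%
    dplyr::mutate(difference = .data$predicted_weekly_minutes -
                    .data$observed_weekly_minutes)
}

#' Agreement between predicted and observed weekly MVPA minutes
#'
#' Full hold-out agreement report: Bland-Altman bias/CI/limits and paired t
#' (via [bland_altman()]), Pearson and Spearman correlations, and the R^2 and
#' residual RMSE of the simple regression of observed on predicted minutes.
#'
#' @param predictions Prediction records from [make_predictions()].
#' @return A `paq_agreement` object carrying the per-participant records
#'   (retrievable with [tidy()]) and the extra association statistics.
#' @export
evaluate_agreement <- function(predictions) {
  assert_columns(predictions,
                 c("predicted_weekly_minutes", "observed_weekly_minutes", "difference"),
                 "predictions")
  out <- bland_altman(predictions$difference)
  p <- predictions$predicted_weekly_minutes
  o <- predictions$observed_weekly_minutes
  fit <- lm(o ~ p)
  out$pearson_r <- cor(p, o)
  out$spearman_r <- cor(p, o, method = "spearman")
  out$r_squared_val <- summary(fit)$r.squared
  out$rmse_val <- sqrt(sum(residuals(fit)^2) / fit$df.residual)
  out$predictions <- predictions
  out
}

#' @export
print.paq_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d participants (predicted - observed, min/week)\n", x$n))
  cat(sprintf("  mean bias %.1f +/- %.1f; 95%% CI (%.1f, %.1f)\n",
              x$mean_bias, x$sd_diff, x$ci95[["lower"]], x$ci95[["upper"]]))
  cat(sprintf("  limits of agreement (%.1f, %.1f)\n",
              x$loa[["lower"]], x$loa[["upper"]]))
  cat(sprintf("  paired t(%d) = %.2f, p = %.3g\n", x$paired_df, x$paired_t, x$paired_p))
  if (!is.null(x$pearson_r)) {
    cat(sprintf("  Pearson r = %.2f; regression R^2 = %.2f, RMSE = %.1f\n",
                x$pearson_r, x$r_squared_val, x$rmse_val))
  }
  invisible(x)
}

#' @rdname evaluate_agreement
#' @param x A `paq_agreement` object.
#' @param ... Unused.
#' @method tidy paq_agreement
#' @export
tidy.paq_agreement <- function(x, ...) {
  x$predictions %||% abort("This agreement report carries no per-participant records.")
}

#' @rdname evaluate_agreement
#' @method glance paq_agreement
#' @export
glance.paq_agreement <- function(x, ...) {
  tibble::tibble(
    n = x$n, mean_bias = x$mean_bias, sd_diff = x$sd_diff, se_bias = x$se_bias,
    ci95_lower = x$ci95[["lower"]], ci95_upper = x$ci95[["upper"]],
    loa_lower = x$loa[["lower"]], loa_upper = x$loa[["upper"]],
    paired_t = x$paired_t, paired_df = x$paired_df, paired_p = x$paired_p,
    pearson_r = x$pearson_r %||% NA_real_,
    spearman_r = x$spearman_r %||% NA_real_,
    r_squared_val = x$r_squared_val %||% NA_real_,
    rmse_val = x$rmse_val %||% NA_real_
  )
}

#' @rdname evaluate_agreement
#' @param object A `paq_agreement` object (for `autoplot`).
#' @method autoplot paq_agreement
#' @export
autoplot.paq_agreement <- function(object, ...) {
  d <- tidy(object)
  d$mean_po <- (d$predicted_weekly_minutes + d$observed_weekly_minutes) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_po, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed") +
    ggplot2::labs(x = "Mean of predicted and observed MVPA (min/week)",
                  y = "Predicted - observed (min/week)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

# Rank (Mann-Whitney) AUC of scores against a binary truth, ties counting 1/2.
rank_auc <- function(scores, truth) {
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Guideline classification agreement
#'
#' Classifies each participant as meeting the weekly MVPA guideline (default
#' 420 min/week, i.e. 60 min/day) from both predicted and observed minutes,
#' taking the accelerometer as truth. Reports the confusion matrix,
#' sensitivity and specificity (percent), and the AUC of predicted minutes
#' against the accelerometer class via the rank (Mann-Whitney) statistic with
#' ties counting one half. If the observations are all one class, the AUC is
#' undefined (`NA`) and a warning is raised.
#'
#' @param predictions Prediction records from [make_predictions()].
#' @param threshold_weekly_minutes Guideline threshold (min/week); being
#'   active means reaching it.
#' @return An object of class `paq_classification` (also a list):
#'   `threshold_weekly_minutes`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity` (percent), `auc`.
#' @export
guideline_classification <- function(predictions, threshold_weekly_minutes = 420) {
  assert_columns(predictions,
                 c("predicted_weekly_minutes", "observed_weekly_minutes"),
                 "predictions")
  assert_number(threshold_weekly_minutes, "threshold_weekly_minutes", lower = 0)
  pred_active <- predictions$predicted_weekly_minutes >= threshold_weekly_minutes
  obs_active <- predictions$observed_weekly_minutes >= threshold_weekly_minutes
  tp <- sum(pred_active & obs_active)
  fp <- sum(pred_active & !obs_active)
  tn <- sum(!pred_active & !obs_active)
  fn <- sum(!pred_active & obs_active)
  if (all(obs_active) || all(!obs_active)) {
    warn("All observations fall in one guideline class; AUC is undefined.")
  }
  structure(list(
    threshold_weekly_minutes = threshold_weekly_minutes,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    auc = rank_auc(predictions$predicted_weekly_minutes, obs_active)
  ), class = "paq_classification")
}

#' @export
print.paq_classification <- function(x, ...) {
  cat(sprintf("Guideline classification at %g min/week\n", x$threshold_weekly_minutes))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
              x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' @rdname guideline_classification
#' @param x A `paq_classification` object.
#' @param ... Unused.
#' @method glance paq_classification
#' @export
glance.paq_classification <- function(x, ...) {
  tibble::tibble(threshold_weekly_minutes = x$threshold_weekly_minutes,
                 tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 auc = x$auc)
}

#' Weekly-minute projection across PAQ scores
#'
#' Evaluates the calibrated PAQ-to-weekly-minutes mapping over a grid of PAQ
#' scores for given ages and sex -- each unit of PAQ adds
#' `coefficients["paq"] / 100 x 5460` weekly minutes (55.1 with the published
#' coefficients).
#'
#' @param paq Grid of PAQ scores.
#' @param age Ages to project (one line each).
#' @param sex Sex code (1 or 2).
#' @param coefficients Calibration coefficients.
#' @param awake_minutes_per_week Weekly awake minutes.
#' @return A tibble `paq`, `age`, `sex`, `weekly_minutes`.
#' @export
project_weekly_minutes <- function(paq = seq(1, 5, by = 0.5),
                                   age = c(9, 11, 13), sex = 1,
                                   coefficients = paq_reference_coefficients(),
                                   awake_minutes_per_week = 5460) {
  grid <- tidyr::expand_grid(paq = paq, age = age, sex = sex)
  grid %>%
    dplyr::mutate(weekly_minutes = pct_to_weekly_minutes(
      predict_pct_mvpa(.data$sex, .data$age, .data$paq, coefficients),
      awake_minutes_per_week))
}

#' @rdname project_weekly_minutes
#' @param projection Output of `project_weekly_minutes()`.
#' @export
plot_weekly_projection <- function(projection = project_weekly_minutes()) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$paq, y = .data$weekly_minutes,
                               colour = factor(.data$age))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PAQ summary score (1-5)", y = "Predicted MVPA (min/week)",
                  colour = "Age (y)",
                  title = "Calibrated PAQ-to-MVPA projection") +
    ggplot2::theme_minimal()
}
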