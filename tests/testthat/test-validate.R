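test_that("the calibration equation predicts, rounds PAQ, and floors at zero", {
  expect_equal(predict_pct_mvpa(1, 9, 3.0), 9.05)
  # linearity: +1 PAQ unit moves the prediction by the PAQ slope
  expect_equal(predict_pct_mvpa(1, 11, 4.2) - predict_pct_mvpa(1, 11, 3.2), 1.01)
  # PAQ is rounded to one decimal before entering the equation
  expect_equal(predict_pct_mvpa(1, 9, 3.04), predict_pct_mvpa(1, 9, 3.0))
  # floor: drive the linear predictor negative with a lowered intercept
  low <- c(intercept = 10, sex = -0.98, age = -0.84, paq = 1.01)
  expect_equal(predict_pct_mvpa(2, 14, 1.0, low), 0)
  expect_error(predict_pct_mvpa(3, 10, 3), "sex")
  expect_warning(predict_pct_mvpa(1, 16, 3), "outside")
  expect_equal(unname(round(predict_pct_mvpa(2, 13, 2.8), 2)), 4.51)
})

test_that("percent-to-minutes conversion uses the 5,460-minute weekly base", {
  expect_equal(round(pct_to_weekly_minutes(1.01), 1), 55.1)
  expect_equal(pct_to_weekly_minutes(0), 0)
  expect_equal(pct_to_weekly_minutes(100), 5460)
  expect_equal(pct_to_weekly_minutes(10, awake_minutes_per_week = 1000), 100)
  # each PAQ unit is worth 55.1 weekly minutes in the projection
  proj <- project_weekly_minutes(paq = c(2, 3), age = 11, sex = 1)
  expect_equal(round(diff(proj$weekly_minutes), 1), 55.1)
})

test_that("observed weekly minutes support both time bases and agree at full wear", {
  persons <- tibble::tibble(pct_mvpa_combined = 7.1,
                            mvpa_min_daily_mean = 7.1 / 100 * 780)
  expect_equal(round(observed_weekly_minutes(persons), 1), 387.7)
  # at 780 wear minutes the minute-based mode gives the identical answer
  expect_equal(observed_weekly_minutes(persons),
               observed_weekly_minutes(persons, mode = "minutes"))
  zero <- tibble::tibble(pct_mvpa_combined = 0, mvpa_min_daily_mean = 0)
  expect_equal(observed_weekly_minutes(zero), 0)
})

test_that("Bland-Altman statistics reproduce the published-scale arithmetic", {
  d <- sample_with_moments(45, mean = 25.3, sd = 121.2)
  ba <- bland_altman(d)
  expect_equal(round(ba$loa[["lower"]], 1), -212.3)
  expect_equal(round(ba$loa[["upper"]], 1), 262.9)
  expect_equal(round(ba$ci95[["upper"]], 1), 61.7)
  expect_equal(round(ba$paired_t, 2), 1.40)
  expect_equal(ba$paired_df, 44)
  expect_gt(ba$paired_p, 0.05)

  const <- bland_altman(rep(4.2, 10))
  expect_equal(const$sd_diff, 0)
  expect_equal(unname(diff(const$loa)), 0)
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("agreement identities hold on arbitrary inputs", {
  withr::local_seed(31)
  for (i in 1:20) {
    d <- rnorm(sample(3:60, 1), sd = runif(1, 0.1, 200))
    ba <- bland_altman(d)
    expect_equal(ba$loa[["lower"]], ba$mean_bias - 1.96 * ba$sd_diff)
    expect_equal(ba$loa[["upper"]], ba$mean_bias + 1.96 * ba$sd_diff)
    expect_equal(ba$ci95[["upper"]] - ba$mean_bias,
                 qt(0.975, ba$n - 1) * ba$sd_diff / sqrt(ba$n))
    expect_equal(ba$paired_t, ba$mean_bias / (ba$sd_diff / sqrt(ba$n)))
    expect_equal(ba$paired_p,
                 t.test(d)$p.value, tolerance = 1e-12)
  }
})

test_that("the hold-out report links correlation and regression R-squared", {
  withr::local_seed(55)
  preds <- tibble::tibble(
    participant_id = sprintf("V%02d", 1:45),
    sex = sample(1:2, 45, TRUE), age = sample(8:14, 45, TRUE),
    paq = runif(45, 1, 5),
    pct_mvpa_combined = runif(45, 2, 12)
  )
  rec <- make_predictions(preds)
  expect_equal(rec$difference,
               rec$predicted_weekly_minutes - rec$observed_weekly_minutes)
  agr <- evaluate_agreement(rec)
  expect_equal(agr$pearson_r^2, agr$r_squared_val, tolerance = 1e-12)
  expect_equal(nrow(tidy(agr)), 45)
  g <- glance(agr)
  expect_true(all(c("mean_bias", "loa_lower", "pearson_r", "rmse_val") %in% names(g)))
})

test_that("guideline classification matches the exhaustive pair-counting oracle", {
  toy <- tibble::tibble(
    participant_id = letters[1:6],
    predicted_weekly_minutes = c(500, 430, 410, 410, 300, 600),
    observed_weekly_minutes = c(450, 500, 300, 430, 200, 410)
  )
  cls <- guideline_classification(toy)
  truth <- toy$observed_weekly_minutes >= 420
  expect_equal(cls$auc, oracle_auc(toy$predicted_weekly_minutes, truth))
  expect_equal(cls$tp + cls$fp + cls$tn + cls$fn, 6)
  expect_equal(cls$sensitivity, 100 * cls$tp / (cls$tp + cls$fn))
  expect_equal(cls$specificity, 100 * cls$tn / (cls$tn + cls$fp))

  # random scores against the oracle, including ties
  withr::local_seed(77)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    score <- sample(1:8, n, replace = TRUE) * 100
    obs <- sample(c(100, 500), n, replace = TRUE)
    if (length(unique(obs)) < 2) obs[1:2] <- c(100, 500)
    p <- tibble::tibble(participant_id = as.character(1:n),
                        predicted_weekly_minutes = score,
                        observed_weekly_minutes = obs)
    expect_equal(guideline_classification(p)$auc,
                 oracle_auc(score, obs >= 420))
  }
})

test_that("AUC is monotone-invariant, 1 under separation, and NA for one class", {
  sep <- tibble::tibble(participant_id = as.character(1:8),
                        predicted_weekly_minutes = c(500, 600, 700, 800, 100, 150, 200, 250),
                        observed_weekly_minutes = c(500, 430, 460, 440, 100, 200, 300, 150))
  cls <- guideline_classification(sep)
  expect_equal(cls$auc, 1)
  expect_equal(cls$sensitivity, 100)
  expect_equal(cls$specificity, 100)
  # strictly monotone transform of the scores leaves the AUC unchanged
  trans <- sep
  trans$predicted_weekly_minutes <- log(trans$predicted_weekly_minutes)^3
  expect_equal(guideline_classification(trans)$auc, 1)

  onecls <- tibble::tibble(participant_id = as.character(1:4),
                           predicted_weekly_minutes = c(500, 100, 450, 80),
                           observed_weekly_minutes = rep(500, 4))
  expect_warning(u <- guideline_classification(onecls), "one guideline class")
  expect_true(is.na(u$auc))

  # predictions unrelated to the outcome sit near 0.5
  withr::local_seed(90)
  big <- tibble::tibble(participant_id = as.character(1:800),
                        predicted_weekly_minutes = runif(800, 0, 900),
                        observed_weekly_minutes = runif(800, 0, 900))
  expect_lt(abs(guideline_classification(big)$auc - 0.5), 0.08)

  # pROC agrees with the rank formulation
  roc <- suppressMessages(pROC::roc(sep$observed_weekly_minutes >= 420,
                                    sep$predicted_weekly_minutes, quiet = TRUE))
  expect_equal(cls$auc, as.numeric(pROC::auc(roc)))
})
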