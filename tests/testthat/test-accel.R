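test_that("epoch CSV round-trips and malformed files are rejected with line numbers", {
  dir <- withr::local_tempdir()
  epochs <- make_epochs(c(0L, 120L, 2000L, 45L), pid = "P9")
  path <- file.path(dir, "P9.csv")
  write_epoch_csv(epochs, path)
  expect_equal(read_epoch_csv(path), epochs)

  bad <- readr::read_lines(path)
  bad[5] <- "2009-10-05T08:00:30,-4"
  readr::write_lines(bad, file.path(dir, "neg.csv"))
  expect_error(read_epoch_csv(file.path(dir, "neg.csv")), "line 5")

  sixty <- c("participant_id,P9", "epoch_seconds,60", "timestamp,counts",
             "2009-10-05T08:00:00,10", "2009-10-05T08:01:00,10")
  readr::write_lines(sixty, file.path(dir, "sixty.csv"))
  expect_error(read_epoch_csv(file.path(dir, "sixty.csv")), "epoch length")

  gap <- readr::read_lines(path)
  gap[7] <- "2009-10-05T08:03:00,7"
  readr::write_lines(gap, file.path(dir, "gap.csv"))
  expect_error(read_epoch_csv(file.path(dir, "gap.csv")), "spacing")
  swap <- readr::read_lines(path)
  swap[6] <- "2009-10-05T08:00:00,7"
  readr::write_lines(swap, file.path(dir, "swap.csv"))
  expect_error(read_epoch_csv(file.path(dir, "swap.csv")), "non-monotone")

  vendor <- c("------------ Data File Created By ActiGraph ------------",
              "Serial Number: XYZ123", readr::read_lines(path))
  readr::write_lines(vendor, file.path(dir, "vendor.csv"))
  expect_error(read_epoch_csv(file.path(dir, "vendor.csv")), "unrecognised")
  expect_equal(read_epoch_csv(file.path(dir, "vendor.csv"),
                              tolerate_vendor_header = TRUE), epochs)
})

test_that("the day window keeps 780 minutes and is half-open at the end", {
  full_day <- make_epochs(rep(10L, 2880), start = "2009-10-05 00:00:00")
  win <- restrict_day_window(full_day)
  expect_equal(nrow(win), 1560)  # 13 h x 2 epochs/min
  expect_equal(min(lubridate::hour(win$timestamp)), 8)
  expect_false(any(format(win$timestamp, "%H:%M") == "21:00"))

  night <- make_epochs(rep(5L, 40), start = "2009-10-05 22:00:00")
  expect_equal(nrow(restrict_day_window(night)), 0)
  edge <- make_epochs(c(7L, 7L), start = "2009-10-05 21:00:00")
  expect_equal(nrow(restrict_day_window(edge)), 0)
  expect_error(restrict_day_window(full_day, "21:00", "08:00"), "precede")
})

test_that("minute aggregation sums epoch pairs and drops unpaired epochs", {
  m <- to_minute_counts(make_epochs(c(40L, 60L)))
  expect_equal(m$cpm, 100)
  zeros <- to_minute_counts(make_epochs(rep(0L, 10)))
  expect_true(all(zeros$cpm == 0))
  odd <- to_minute_counts(make_epochs(c(40L, 60L, 30L)))
  expect_equal(nrow(odd), 1)  # trailing unpaired epoch not aggregated
})

test_that("non-wear detection applies the 90-minute rule with the low-count allowance", {
  expect_true(all(!detect_nonwear(make_minutes(rep(0, 780)))$wear))
  flanked89 <- make_minutes(c(500, rep(0, 89), 500))
  expect_true(all(detect_nonwear(flanked89)$wear))
  # 90 zeros qualify even when flanked by activity
  flanked90 <- make_minutes(c(500, rep(0, 90), 500))
  expect_equal(sum(!detect_nonwear(flanked90)$wear), 90)
  # allowance: 2 low-count minutes keep the bout alive, 3 break it
  absorbed <- make_minutes(c(rep(0, 50), 50, 50, rep(0, 48)))
  expect_equal(sum(!detect_nonwear(absorbed)$wear), 100)
  broken <- make_minutes(c(rep(0, 50), 50, 50, 50, rep(0, 48)))
  expect_true(all(detect_nonwear(broken)$wear))
  # a minute above the ceiling always terminates the candidate
  high <- make_minutes(c(rep(0, 50), 101, rep(0, 48)))
  expect_true(all(detect_nonwear(high)$wear))
  expect_equal(nrow(detect_nonwear(make_minutes(numeric(0)))), 0)
})

test_that("non-wear detection matches the regex oracle on random traces", {
  withr::local_seed(1204)
  for (i in 1:250) {
    cpm <- random_cpm_trace(780)
    got <- !detect_nonwear(make_minutes(cpm))$wear
    expect_identical(got, oracle_nonwear_regex(cpm))
  }
  # partition invariant comes for free: the mask covers every minute
  m <- detect_nonwear(make_minutes(random_cpm_trace(780)))
  expect_equal(sum(m$wear) + sum(!m$wear), 780)
})

test_that("age-specific cut points invert the MET equation", {
  expect_equal(mvpa_cutpoint_cpm(10), 1910)  # 4 METs, Freedson age model
  expect_equal(epoch_threshold(mvpa_cutpoint_cpm(10)), 955)
  # closed-form check across the age range
  for (age in 8:14) {
    cpm <- mvpa_cutpoint_cpm(age, round_threshold = FALSE)
    met <- 2.757 + 0.0015 * cpm - 0.08957 * age - 0.000038 * cpm * age
    expect_equal(met, 4, tolerance = 1e-10)
  }
  # threshold collapses to zero when the MET floor equals the zero-cpm value
  met0 <- 2.757 - 0.08957 * 10
  expect_equal(mvpa_cutpoint_cpm(10, met_threshold = met0), 0)
  # a user table is passed through verbatim
  expect_equal(mvpa_cutpoint_cpm(c(9, 12), cutpoint_table = c(`9` = 1500, `12` = 1800)),
               c(1500, 1800))
  expect_warning(mvpa_cutpoint_cpm(15), "outside")
})

test_that("MVPA classification requires the threshold and wear time", {
  epochs <- make_epochs(rep(c(100L, 1200L), 10))
  minutes <- detect_nonwear(to_minute_counts(epochs))
  cls <- classify_mvpa(epochs, minutes, epoch_threshold = 955)
  expect_equal(sum(cls$mvpa) / 2, 5)  # 10 epochs above threshold -> 5 min
  expect_equal(sum(classify_mvpa(epochs, minutes, epoch_threshold = 2000)$mvpa), 0)

  # epochs above threshold inside a non-wear bout are not counted
  cpm <- c(rep(0, 45), 50, rep(0, 45))           # one 91-min non-wear run
  ep <- make_epochs(as.integer(rep(cpm / 2, each = 2)))
  ep$counts[60] <- 2000L                          # spike inside the zero run
  min2 <- detect_nonwear(to_minute_counts(make_epochs(as.integer(rep(cpm / 2, each = 2)))))
  cls2 <- classify_mvpa(ep, min2, epoch_threshold = 955)
  expect_equal(sum(cls2$mvpa), 0)

  # lowering the cut point never decreases MVPA minutes
  withr::local_seed(7)
  ep3 <- make_epochs(sample(0:2500, 400, replace = TRUE))
  min3 <- detect_nonwear(to_minute_counts(ep3))
  mv <- vapply(c(1200, 955, 700, 300), function(thr)
    sum(classify_mvpa(ep3, min3, thr)$mvpa), numeric(1))
  expect_true(all(diff(mv) >= 0))
})

test_that("day summaries enforce the 546-minute validity boundary", {
  at_boundary <- summarize_day(make_classified_day(wear_epochs = 1092, mvpa_epochs = 40))
  expect_true(at_boundary$valid)
  expect_equal(at_boundary$wear_minutes, 546)
  below <- summarize_day(make_classified_day(wear_epochs = 1090, mvpa_epochs = 40))
  expect_equal(below$wear_minutes, 545)
  expect_false(below$valid)

  full <- summarize_day(make_classified_day(wear_epochs = 1560, mvpa_epochs = 156))
  expect_equal(full$pct_mvpa, 10)
  expect_equal(full$mvpa_minutes, 78)
  expect_false(full$is_weekend)  # 2009-10-05 is a Monday

  nowear <- summarize_day(make_classified_day(wear_epochs = 0, mvpa_epochs = 0))
  expect_true(is.na(nowear$pct_mvpa))
  # MVPA never exceeds wear
  expect_true(all(at_boundary$mvpa_minutes <= at_boundary$wear_minutes))
})

test_that("week summaries apply the 4-day/3-weekday/1-weekend rule and weighting", {
  base <- as.Date("2009-10-05")  # Monday
  mk_days <- function(pcts, dates, valid = TRUE) {
    tibble::tibble(participant_id = "W1", date = dates,
                   is_weekend = lubridate::wday(dates, week_start = 1) >= 6,
                   wear_minutes = 700, mvpa_minutes = pcts / 100 * 700,
                   pct_mvpa = pcts, cpm_mean = 400,
                   valid = valid)
  }
  flat <- summarize_week(mk_days(rep(8, 7), base + 0:6))
  expect_true(flat$week_valid)
  expect_equal(flat$pct_mvpa_combined, 8)

  mixed <- summarize_week(mk_days(c(rep(7, 5), 0, 0), base + 0:6))
  expect_equal(mixed$pct_mvpa_combined, 5)  # (5*7 + 2*0)/7
  # with 4 weekdays + 1 weekend day the two combination rules diverge
  uneven <- mk_days(c(rep(7, 4), 0), base + c(0, 1, 2, 3, 5))
  expect_equal(summarize_week(uneven)$pct_mvpa_combined, 5)
  expect_equal(summarize_week(uneven, combine = "unweighted")$pct_mvpa_combined, 5.6)

  ok <- summarize_week(mk_days(rep(8, 4), base + c(0, 1, 2, 5)))   # 3 wk + 1 we
  expect_true(ok$week_valid)
  nowe <- summarize_week(mk_days(rep(8, 4), base + 0:3))           # 4 weekdays
  expect_false(nowe$week_valid)
  expect_true(is.na(nowe$pct_mvpa_combined))
  threeday <- summarize_week(mk_days(rep(8, 3), base + c(0, 1, 5)))
  expect_false(threeday$week_valid)
})
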