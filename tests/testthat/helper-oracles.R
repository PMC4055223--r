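# Independent oracles and small fixture builders shared across tests.

# Regex statement of the non-wear rule: maximal runs of zeros broken only by
# interior interruptions of <= allow_max low-count minutes, total >= min_bout.
oracle_nonwear_regex <- function(cpm, min_bout = 90, allow_max = 2, ceiling = 100) {
  code <- ifelse(cpm == 0, "z", ifelse(cpm <= ceiling, "a", "h"))
  s <- paste(code, collapse = "")
  pat <- sprintf("z+(?:a{1,%d}z+)*", allow_max)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  mask <- logical(length(cpm))
  if (m[1] != -1) {
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      if (len[k] >= min_bout) mask[m[k]:(m[k] + len[k] - 1)] <- TRUE
    }
  }
  mask
}

# Normal-equations least squares (X includes the intercept column).
oracle_ols <- function(X, y) unname(drop(solve(t(X) %*% X, t(X) %*% y)))

# Exhaustive pair-counting AUC with ties worth 1/2.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Minute-level tibble for one day starting 08:00 from a cpm vector.
make_minutes <- function(cpm, pid = "T1", date = as.Date("2009-10-05")) {
  start <- lubridate::as_datetime(date, tz = "UTC") + 8 * 3600
  tibble::tibble(participant_id = pid, date = date,
                 minute = start + 60 * (seq_along(cpm) - 1), cpm = cpm)
}

# Epoch tibble from a counts vector at 30-s spacing.
make_epochs <- function(counts, pid = "T1", start = "2009-10-05 08:00:00") {
  t0 <- lubridate::ymd_hms(start, tz = "UTC")
  tibble::tibble(participant_id = pid,
                 timestamp = t0 + 30 * (seq_along(counts) - 1),
                 counts = as.integer(counts))
}

# Random one-day cpm trace that mixes zeros, low counts and activity.
random_cpm_trace <- function(n = 780) {
  sample(c(0L, 1L, 50L, 100L, 101L, 500L, 2500L), n, replace = TRUE,
         prob = c(0.55, 0.05, 0.1, 0.05, 0.05, 0.1, 0.1))
}

# Rescale a normal draw to exact sample mean and SD.
sample_with_moments <- function(n, mean, sd, seed = 1) {
  x <- withr::with_seed(seed, rnorm(n))
  mean + sd * (x - mean(x)) / stats::sd(x)
}

# Classified-epoch tibble with prescribed wear / MVPA epoch counts for one day.
make_classified_day <- function(wear_epochs, mvpa_epochs, pid = "T1",
                                date = as.Date("2009-10-05"), total_epochs = 1560) {
  stopifnot(mvpa_epochs <= wear_epochs, wear_epochs <= total_epochs)
  wear <- c(rep(TRUE, wear_epochs), rep(FALSE, total_epochs - wear_epochs))
  mvpa <- c(rep(TRUE, mvpa_epochs), rep(FALSE, total_epochs - mvpa_epochs))
  counts <- ifelse(mvpa, 2000L, ifelse(wear, 300L, 0L))
  start <- lubridate::as_datetime(date, tz = "UTC") + 8 * 3600
  tibble::tibble(participant_id = pid,
                 timestamp = start + 30 * (seq_len(total_epochs) - 1),
                 counts = counts, wear = wear, mvpa = mvpa)
}
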