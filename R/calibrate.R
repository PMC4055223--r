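# Calibration-sample construction, the %MVPA regression, and its diagnostics.

#' Split a sample into calibration and validation sets
#'
#' Randomly assigns participants to a calibration set (fraction `frac`,
#' default 70%) and a hold-out validation set, reproducibly for a given seed.
#' With `stratify_by`, the fractions hold within each stratum (to within one
#' participant), e.g. to balance fall and spring observations across the two
#' sets.
#'
#' @param data Data frame with one row per participant.
#' @param frac Calibration fraction, in (0, 1).
#' @param seed Integer seed.
#' @param stratify_by Optional column name (string) to stratify on.
#' @return `data` with an added `split` column (`"calibration"` /
#'   `"validation"`).
#' @examples
#' roster <- tibble::tibble(participant_id = sprintf("P%03d", 1:148))
#' table(split_sample(roster, seed = 1)$split)  # 103 / 45
#' @export
split_sample <- function(data, frac = 0.70, seed = 1L, stratify_by = NULL) {
  assert_fraction(frac, "frac")
  n <- nrow(data)
  if (n < 10) abort("Need at least 10 participants to form a split.")
  with_seed(seed, {
    if (is.null(stratify_by)) {
      n_cal <- floor(frac * n)
      idx <- sample.int(n, n_cal)
      data$split <- "validation"
      data$split[idx] <- "calibration"
    } else {
      assert_columns(data, stratify_by, "data")
      strata <- data[[stratify_by]]
      data$split <- "validation"
      for (s in unique(strata)) {
        rows <- which(strata == s)
        n_cal <- round(frac * length(rows))
        data$split[sample(rows, n_cal)] <- "calibration"
      }
    }
    if (!any(data$split == "validation")) {
      abort("Split leaves the validation set empty; lower `frac`.")
    }
    if (!any(data$split == "calibration")) {
      abort("Split leaves the calibration set empty; raise `frac`.")
    }
  })
  data
}

calibration_predictors <- function(include_bmi) {
  c("sex", "age", "paq", if (include_bmi) "bmi")
}

#' Fit the %MVPA calibration regression
#'
#' Ordinary least squares of percent wear time in MVPA on sex (coded 1 =
#' male, 2 = female), age in whole years, and the PAQ summary score (rounded
#' to one decimal place before entering the model, matching the instrument's
#' reporting convention). Standard errors use the unbiased residual variance
#' with `n - p` degrees of freedom; the residual RMSE is
#' `sqrt(SSE / (n - p))`, i.e. the square root of the mean-square residual of
#' the regression ANOVA. BMI (kg/m^2) can be added as an optional fourth
#' predictor to reproduce its non-significance check.
#'
#' @param data Data frame with columns `pct_mvpa`, `sex`, `age`, `paq` (and
#'   `bmi` if requested).
#' @param include_bmi Add BMI as a predictor.
#' @return An object of class `paq_calibration` with [tidy()], [glance()],
#'   [predict()][predict.paq_calibration] and [autoplot()] methods.
#' @export
fit_calibration <- function(data, include_bmi = FALSE) {
  preds <- calibration_predictors(include_bmi)
  assert_columns(data, c("pct_mvpa", preds), "calibration data")
  d <- dplyr::as_tibble(data[, c("pct_mvpa", preds)])
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n <= 5) abort("Calibration requires more than 5 complete observations.")
  d$paq <- round(d$paq, 1)
  constant <- preds[vapply(d[preds], function(x) var(x) == 0, logical(1))]
  if (length(constant)) {
    abort(sprintf("Predictor(s) constant in the sample: %s.",
                  paste(constant, collapse = ", ")))
  }
  fml <- stats::reformulate(preds, response = "pct_mvpa")
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(sprintf("Singular design: %s aliased with other predictors.",
                  paste(aliased, collapse = ", ")))
  }
  structure(list(fit = fit, data = d, predictors = preds, n = n),
            class = "paq_calibration")
}

#' @export
print.paq_calibration <- function(x, ...) {
  cat("%MVPA calibration model (OLS)\n")
  cat(sprintf("  n = %d, predictors: %s\n", x$n, paste(x$predictors, collapse = ", ")))
  print(tidy(x), ...)
  g <- glance(x)
  cat(sprintf("  R^2 = %.3f, RMSE = %.3f, AIC = %.2f\n", g$r_squared, g$rmse, g$aic))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `paq_calibration` object.
#' @param ... Unused.
#' @method tidy paq_calibration
#' @export
tidy.paq_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", rownames(s)[-1]),
                 estimate = unname(s[, 1]), std_error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p_value = unname(s[, 4]))
}

#' @rdname fit_calibration
#' @method glance paq_calibration
#' @export
glance.paq_calibration <- function(x, ...) {
  fit <- x$fit
  sse <- sum(residuals(fit)^2)
  v <- vif_values(x)
  bp <- breusch_pagan(x)
  tibble::tibble(
    n = x$n,
    r_squared = summary(fit)$r.squared,
    rmse = sqrt(sse / fit$df.residual),
    aic = model_aic(x),
    vif_min = min(v), vif_max = max(v),
    bp_statistic = bp$statistic, bp_df = bp$df, bp_p = bp$p_value,
    df_residual = fit$df.residual
  )
}

#' Predict percent MVPA from a fitted calibration model
#'
#' @param object A `paq_calibration` object.
#' @param newdata Data frame with the model's predictor columns.
#' @param ... Unused.
#' @return Predicted %MVPA, floored at 0 (PAQ rounded to one decimal first).
#' @export
predict.paq_calibration <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  newdata$paq <- round(newdata$paq, 1)
  pmax(0, unname(stats::predict(object$fit, newdata = newdata)))
}

#' Gaussian AIC of a calibration model
#'
#' `AIC = n log(SSE / n) + 2k`, with `k` counting the regression coefficients
#' plus the residual variance. Only differences between models fitted to the
#' same data are meaningful.
#'
#' @param x A `paq_calibration` object or an `lm` fit.
#' @return The AIC value (dimensionless).
#' @export
model_aic <- function(x) {
  fit <- if (inherits(x, "paq_calibration")) x$fit else x
  sse <- sum(residuals(fit)^2)
  n <- length(residuals(fit))
  k <- length(coef(fit)) + 1
  n * log(sse / n) + 2 * k
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on the remaining predictors (with intercept). A predictor perfectly
#' explained by the others is reported as `Inf` with a warning.
#'
#' @param x A `paq_calibration` object, or a data frame / matrix of predictor
#'   columns (no intercept column).
#' @return Named vector of VIFs, one per predictor.
#' @export
vif_values <- function(x) {
  X <- if (inherits(x, "paq_calibration")) {
    as.matrix(x$data[, x$predictors])
  } else {
    as.matrix(x)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2) abort("VIF needs at least two predictors.")
  out <- vapply(seq_len(ncol(X)), function(j) {
    aux <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(aux$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) {
      warn(sprintf("Predictor %s is singular with the others; VIF is infinite.",
                   colnames(X)[j]))
      Inf
    } else {
      1 / (1 - r2)
    }
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Lagrange-multiplier test of constant residual variance, in the studentized
#' (Koenker) form `LM = n R^2` from regressing squared residuals on an
#' auxiliary design. `variant = "bp"` uses the model's own predictors
#' (df = number of predictors). `variant = "white"` (default) uses the
#' predictors, their squares and pairwise products, dropping any term aliased
#' with columns already present -- for the sex/age/PAQ design with binary sex
#' (sex^2 is an affine function of sex), that leaves 8 degrees of freedom.
#'
#' @param x A `paq_calibration` object.
#' @param variant `"white"` or `"bp"`.
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p_value`,
#'   `variant`.
#' @export
breusch_pagan <- function(x, variant = c("white", "bp")) {
  variant <- match.arg(variant)
  stopifnot(inherits(x, "paq_calibration"))
  X <- as.matrix(x$data[, x$predictors])
  e2 <- residuals(x$fit)^2
  n <- length(e2)
  aux <- X
  if (variant == "white") {
    sq <- X^2
    colnames(sq) <- paste0(colnames(X), "_sq")
    cross <- NULL
    cn <- colnames(X)
    for (a in seq_len(ncol(X) - 1)) {
      for (b in seq((a + 1), ncol(X))) {
        cross <- cbind(cross, X[, a] * X[, b])
        colnames(cross)[ncol(cross)] <- paste0(cn[a], "_x_", cn[b])
      }
    }
    aux <- cbind(X, sq, cross)
    # drop terms aliased with columns already kept (rank-increasing only)
    keep <- logical(ncol(aux))
    M <- matrix(1, n, 1)
    for (j in seq_len(ncol(aux))) {
      cand <- cbind(M, aux[, j])
      if (qr(cand)$rank > ncol(M)) {
        keep[j] <- TRUE
        M <- cand
      }
    }
    aux <- aux[, keep, drop = FALSE]
  }
  af <- lm.fit(cbind(1, aux), e2)
  if (any(is.na(af$coefficients))) abort("Auxiliary regression is singular.")
  r2 <- 1 - sum(af$residuals^2) / sum((e2 - mean(e2))^2)
  stat <- n * r2
  df <- ncol(aux)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 variant = variant)
}

#' @rdname fit_calibration
#' @param object A `paq_calibration` object (for `autoplot`).
#' @method autoplot paq_calibration
#' @export
autoplot.paq_calibration <- function(object, ...) {
  d <- tibble::tibble(observed = object$data$pct_mvpa,
                      predicted = fitted(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Predicted %MVPA", y = "Recorded %MVPA",
                  title = "Calibration-sample fit") +
    ggplot2::theme_minimal()
}
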