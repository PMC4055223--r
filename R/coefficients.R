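#' Published PAQ calibration coefficients
#'
#' Coefficients of the published youth calibration equation mapping sex, age
#' and PAQ summary score to daily percent time in MVPA:
#'
#' \deqn{\%MVPA = 14.56 - 0.98\,\mathrm{sex} - 0.84\,\mathrm{age} + 1.01\,\mathrm{PAQ}}
#'
#' Sex is coded 1 for boys and 2 for girls (so the equation's intercept
#' already absorbs one "unit" of sex for boys); age is in whole years over
#' 8--14; PAQ is the 1--5 summary score rounded to one decimal place. The
#' values ship as a plain-text constants file so prediction works without
#' refitting.
#'
#' @return A named numeric vector with elements `intercept`, `sex`, `age`,
#'   `paq`, in units of percentage points of wear time in MVPA.
#' @examples
#' paq_reference_coefficients()
#' @export
paq_reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.csv", package = "paqcal")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$estimate, tab$term)
}
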