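# Internal argument checks shared across modules.

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

assert_fraction <- function(x, name) assert_number(x, name, 0, 1)

assert_count <- function(x, name, lower = 0) {
  assert_number(x, name, lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Inverse-CDF draw from a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' @importFrom stats pnorm qnorm
NULL

# Parse "HH:MM" into minutes after midnight.
parse_clock <- function(x, name) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) abort(sprintf("`%s` must be a clock time like \"08:00\".", name))
  as.integer(m[2]) * 60L + as.integer(m[3])
}
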