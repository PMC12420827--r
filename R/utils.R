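# Internal helpers shared across modules.

# Days per month in the model's 365-day calendar (no leap days).
DAYS_PER_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_OF_DOY <- rep.int(1:12, DAYS_PER_MONTH)

# Evaluate `code` under an explicit integer seed, restoring the caller's RNG
# state afterwards. Every stochastic entry point in the package funnels
# through this so results are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("an explicit finite integer `seed` is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (keeps values < 2^31).
seed_stream <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_cols <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}
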