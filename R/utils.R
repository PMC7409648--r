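# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# All package randomness (splits, generators, calibration loops) goes
# through here so that a seed fully determines the result.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a non-negative finite numeric vector; `what` names the field in
# the error message so callers can report which input failed.
check_nonneg <- function(x, what, allow_na = FALSE) {
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric", what), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("'%s' contains missing values", what), call. = FALSE)
  }
  bad <- !is.na(x) & (!is.finite(x) | x < 0)
  if (any(bad)) {
    stop(sprintf("'%s' must be finite and >= 0 (offending value: %s)",
                 what, format(x[bad][1L])), call. = FALSE)
  }
  invisible(x)
}

check_event <- function(x, what) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must be 0 (censored) or 1 (event), no missing values",
                 what), call. = FALSE)
  }
  invisible(x)
}
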