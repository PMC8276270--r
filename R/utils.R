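#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors name the offending
# field so config mistakes are diagnosable from the message alone.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (strict && x <= lower)
    abort_field(field, sprintf("must be > %s", lower))
  if (!strict && x < lower)
    abort_field(field, sprintf("must be >= %s", lower))
  invisible(x)
}

assert_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    abort_field(field, sprintf("must be an integer >= %d", lower))
  invisible(as.integer(x))
}

assert_increasing <- function(x, field, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x)))
    abort_field(field, "must be a finite numeric vector")
  if (length(x) > 1L && any(diff(x) <= 0))
    abort_field(field, "must be strictly increasing")
  if (nonneg && any(x < 0))
    abort_field(field, "must be nonnegative")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  All generators funnel through this so
# seeded determinism holds regardless of ambient RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    assert_count(seed, "seed", lower = 0L)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
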