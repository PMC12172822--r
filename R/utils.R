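# Internal helpers: seeded RNG streams and small validators.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a base seed and integer stream ids.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (id in ids) {
    x <- (x * 48271 + as.numeric(id) + 1) %% 2147483647
  }
  as.integer(x)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s.",
      name, x, if (strict_min) "(" else "[", min, max,
      if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

as_series_matrix <- function(series, arg = "series") {
  if (is.data.frame(series)) {
    series <- as.matrix(series)
  }
  if (!is.matrix(series) || !is.numeric(series)) {
    abort(sprintf("`%s` must be a numeric frames x nodes matrix.", arg))
  }
  if (anyNA(series) || !all(is.finite(series))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  series
}
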