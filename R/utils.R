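# internal validation / RNG helpers

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_validation("`%s` must be TRUE or FALSE", name)
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("`%s` must be a single finite number", name)
  if (integer && x != round(x))
    stop_validation("`%s` must be an integer, got %s", name, format(x))
  if (strict_lower) {
    if (x <= lower) stop_validation("`%s` must be > %s", name, format(lower))
  } else if (x < lower) {
    stop_validation("`%s` must be >= %s", name, format(lower))
  }
  if (x > upper) stop_validation("`%s` must be <= %s", name, format(upper))
  if (integer) as.integer(x) else as.numeric(x)
}

check_finite_array <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_validation("`%s` must contain only finite values", name)
  invisible(x)
}

# Deterministic stream splitting: derives a child seed (< 2^31) from a base
# seed and an index, so per-clip generation is order-independent.  All
# arithmetic stays exact in double precision.
derive_seed <- function(base, index) {
  as.integer((((base %% 97651) + 1) * 21841 + index * 7919 + 1) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
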