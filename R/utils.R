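# Internal helpers: argument checking and seeded substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower) stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper) stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Centered running mean; the ends fall back to the raw values.
running_mean <- function(x, k) {
  f <- stats::filter(x, rep(1 / k, k), sides = 2)
  i <- is.na(f)
  f[i] <- x[i]
  as.numeric(f)
}

# Deterministic substream seed derived from a root seed and labels.
# Polynomial rolling hash over the label characters, folded into [0, 2^31).
# Keeps every random draw reproducible per (root seed, purpose, id) without
# consuming the global RNG stream in an order-dependent way.
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a locally-seeded RNG, restoring global state afterwards.
with_substream <- function(seed, expr) {
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
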