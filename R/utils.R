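# Internal helpers shared across modules.

# Evaluate expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched so generator calls are referentially transparent.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derived sub-seeds stay inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0) stop_arg(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_arg(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))
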