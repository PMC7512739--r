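# Internal helpers shared across modules.

# Run `expr` under a given seed without disturbing the caller's RNG stream.
# Every stochastic operation in the package takes an explicit seed and goes
# through this helper, so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# Wrap coordinates into [0, L0).
wrap_coords <- function(x, L0) {
  w <- x %% L0
  w[w >= L0] <- 0
  w
}

fmt_num <- function(x) sprintf("%.17g", x)
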