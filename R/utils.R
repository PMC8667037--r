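# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (k in seq_along(idx)) s <- (s * 69069 + as.double(idx[k]) * 2654435761) %% 2147483647
  as.integer(max(1, s))
}

# Smallest signed angular difference, in (-pi, pi].
angle_diff <- function(a, b) atan2(sin(a - b), cos(a - b))
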