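# Internal numeric helpers shared across modules.

# Gyromagnetic ratio of 1H in Hz per Gauss.
GAMMA_H <- 4257.7

fftshift <- function(x) {
  n <- length(x)
  x[c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))]
}

ifftshift <- function(x) {
  n <- length(x)
  x[c(seq(ceiling(n / 2) + 1L, n), seq_len(ceiling(n / 2)))]
}

# Complex white Gaussian noise, sd `sigma` per real/imaginary component.
complex_noise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma),
          imaginary = stats::rnorm(n, sd = sigma))
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
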