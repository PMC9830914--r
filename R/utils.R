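# internal helpers shared across modules

# Enumerate integer pixel offsets (dy, dx) with dy^2 + dx^2 <= r2max,
# sorted by increasing squared distance. Used for exact Euclidean
# dilations: coordinates are integer, so squared distances are exact.
disk_offsets <- function(r2max) {
  r <- floor(sqrt(r2max))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g$d2 <- g$dy^2 + g$dx^2
  g <- g[g$d2 <= r2max, , drop = FALSE]
  g[order(g$d2, g$dy, g$dx), , drop = FALSE]
}

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lognormal multiplicative factor with mean 1 and coefficient of variation cv
rlnorm_cv1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# additive Gaussian noise clipped at zero (intensities are non-negative)
add_noise <- function(x, noise_sd) {
  if (noise_sd <= 0) return(x)
  pmax(x + stats::rnorm(length(x), sd = noise_sd), 0)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a %s scalar", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
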