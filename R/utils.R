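# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Wrapped-Cauchy draws with mean direction mu and concentration rho in [0, 1].
# rho = 0 is uniform on the circle; rho = 1 is a point mass at mu.
rwrapcauchy <- function(n, mu = 0, rho = 0.5) {
  if (rho >= 1) return(rep(mu, n))
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  u <- stats::runif(n)
  wrap_angle(mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}
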