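# Shared fixtures and oracles for the test suite.

# Relative adjoint-identity error |<Kx,y> - <x,K'y>| / |<x,K'y>| on a
# random probe pair.
adjoint_relerr <- function(K, seed = 1L) {
  x <- random_like(K$domain, seed = seed)
  y <- random_like(K$range, seed = seed + 1000L)
  a <- inner_prod(op_apply(K, x), y)
  b <- inner_prod(x, op_adjoint(K, y))
  abs(a - b) / max(abs(b), .Machine$double.eps)
}

# Brute-force scalar prox oracle: minimize 0.5 (v - x)^2 + tau * f(v)
# over a fine grid.
prox_oracle_1d <- function(x, tau, f, lo = -10, hi = 10, n = 200001L) {
  v <- seq(lo, hi, length.out = n)
  v[which.min(0.5 * (v - x)^2 + tau * f(v))]
}

# Check prox optimality: the prox value must beat random perturbation
# candidates in the prox objective.
prox_beats_candidates <- function(f, x, tau, n_cand = 100L, scale = 0.5,
                                  seed = 99L) {
  p <- fn_prox(f, x, tau)
  obj <- function(v) {
    fv <- fn_evaluate(f, v)
    if (!is.finite(fv)) return(Inf)
    fv + (1 / (2 * tau)) * inner_prod(v - x, v - x)
  }
  base <- obj(p)
  set.seed(seed)
  for (k in seq_len(n_cand)) {
    cand <- map_values(p, function(v) v + stats::rnorm(length(v), sd = scale))
    if (obj(cand) < base - 1e-9) return(FALSE)
  }
  TRUE
}

# Pixel-averaged (anti-aliased) disc on a normalized [-1, 1] grid.
aa_disc <- function(size, cx = 0, cy = 0, r = 0.6, supersample = 4L) {
  n <- size * supersample
  big <- outer(seq(-1, 1, length.out = n), seq(-1, 1, length.out = n),
               function(y, x) ((x - cx)^2 + (y - cy)^2 <= r^2) + 0)
  m <- matrix(0, size, size)
  for (i in seq_len(size)) for (j in seq_len(size))
    m[i, j] <- mean(big[((i - 1) * supersample + 1):(i * supersample),
                        ((j - 1) * supersample + 1):(j * supersample)])
  m
}

rand_image <- function(shape, C = 1L, seed = 1L) {
  g <- image_geometry(shape, C)
  random_like(allocate(g, 0), seed = seed)
}
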