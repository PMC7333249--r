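# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the hull oracle enumerates chords, the VIP
# oracle evaluates the formula term by term, the truncated-normal oracle
# integrates the density numerically.

# O(n^3) upper concave envelope: at each band, the envelope equals the
# maximum over all chords between data points whose x-range covers it
# (including the point itself).
brute_force_upper_envelope <- function(x, y) {
  n <- length(x)
  env <- y
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (x[j] <= x[i] && x[i] <= x[k] && j != k) {
          chord <- y[j] + (y[k] - y[j]) * (x[i] - x[j]) / (x[k] - x[j])
          if (chord > env[i]) env[i] <- chord
        }
      }
    }
  }
  env
}

# literal term-by-term VIP formula: sqrt(p * sum_a SSY_a (w_ja/|w_a|)^2 /
# sum_a SSY_a), SSY_a = q_a^2 t_a't_a
vip_formula_oracle <- function(W, q, tss) {
  p <- nrow(W)
  A <- ncol(W)
  ssy <- numeric(A)
  for (a in seq_len(A)) ssy[a] <- q[a]^2 * tss[a]
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      wnorm <- sqrt(sum(W[, a]^2))
      acc <- acc + ssy[a] * (W[j, a] / wnorm)^2
    }
    vip[j] <- sqrt(p * acc / sum(ssy))
  }
  vip
}

# truncated-normal mean and SD by numerical integration of the density
truncnorm_integration_oracle <- function(mu, sigma, a, b) {
  z <- integrate(function(t) dnorm(t, mu, sigma), a, b)$value
  m <- integrate(function(t) t * dnorm(t, mu, sigma), a, b)$value / z
  v <- integrate(function(t) (t - m)^2 * dnorm(t, mu, sigma), a, b)$value / z
  c(mean = m, sd = sqrt(v))
}

# small reflectance dataset wrapper for transform/preprocessing tests
toy_dataset <- function(values, wavelengths = NULL, leaf_n = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1L)
  if (is.null(wavelengths)) wavelengths <- 400 + seq_len(ncol(m)) - 1
  if (is.null(leaf_n)) leaf_n <- seq(2, 3, length.out = nrow(m))
  spectral_dataset(wavelengths, m, leaf_n)
}

# smooth random positive spectra for hull property tests
random_spectrum <- function(p) {
  x <- seq(0, 1, length.out = p)
  y <- 0.3 + 0.2 * sin(2 * pi * runif(1) + x * runif(1, 2, 9)) +
    cumsum(rnorm(p, 0, 0.02))
  pmin(pmax(y, 0.05), 0.95)
}

study_seed <- 42L
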