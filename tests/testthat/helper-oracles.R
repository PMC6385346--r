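# independent oracles used across test files

# closed-form eigendecomposition of the 2x2 covariance of two standardized
# (divisor-n) series: eigenvalues 1 +/- |r|, leading eigenvector along
# (1, sign(r)) / sqrt(2); omega oriented with positive first loading
oracle_pca <- function(a, b) {
  za <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  zb <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
  r <- mean(za * zb)
  u1 <- c(1, sign(r)) / sqrt(2)
  list(
    lambda = c(1 + abs(r), 1 - abs(r)),
    u1 = u1,
    omega = za * u1[1] + zb * u1[2]
  )
}

# brute-force Kendall S by explicit pair count
oracle_kendall_s <- function(v) {
  n <- length(v)
  s <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(v[j] - v[i])
  s
}

# Monte-Carlo sampler for the constrained PDF: draw x from the observation
# PDF, then y | x from the conditional Gaussian around the line
oracle_constrain_samples <- function(obs_mean, obs_sd, slope, intercept,
                                     sigma_f, n = 1e6) {
  x <- rnorm(n, obs_mean, obs_sd)
  sf <- if (is.function(sigma_f)) sigma_f(x) else sigma_f
  intercept + slope * x + rnorm(n, 0, sf)
}

# trapezoid rule (re-derived here, independent of package internals)
trapz_test <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Kolmogorov distance between a gridded density and a sample
ks_grid_vs_sample <- function(y, density, samples) {
  dy <- diff(y)
  cdf <- c(0, cumsum((density[-1] + density[-length(density)]) / 2 * dy))
  cdf <- cdf / cdf[length(cdf)]
  emp <- ecdf(samples)(y)
  max(abs(cdf - emp))
}

# small station record helper (plain tibble from the generator formula)
make_station_record <- function(years, baseline = 330, trend = 1.7,
                                amplitude = 8, deepening = 0, phase = 12,
                                noise_sd = 0, seed = 1) {
  cfg <- station_config(years = years, baseline = baseline, trend = trend,
                        amplitude = amplitude, deepening = deepening,
                        phase = phase, noise_sd = noise_sd, seed = seed)
  sim_station(cfg)
}
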