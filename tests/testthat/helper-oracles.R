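# Independent oracles and small fixture builders shared across tests.

# Brute-force bilinear interpolation: scalar, loop-based, written against
# the textbook formula and kept independent of interpolate_at().
oracle_bilinear <- function(xs, zs, m, xq, zq) {
  i <- max(which(xs <= xq + 1e-15)); i <- min(i, length(xs) - 1L)
  k <- max(which(zs <= zq + 1e-15)); k <- min(k, length(zs) - 1L)
  tx <- (xq - xs[i]) / (xs[i + 1] - xs[i])
  tz <- (zq - zs[k]) / (zs[k + 1] - zs[k])
  (1 - tx) * (1 - tz) * m[i, k] + tx * (1 - tz) * m[i + 1, k] +
    (1 - tx) * tz * m[i, k + 1] + tx * tz * m[i + 1, k + 1]
}

# AR(1) record with exact exponential autocorrelation exp(-lag/tau).
ar1_series <- function(n, fs, mean_u, sd_u, tau, seed) {
  set.seed(seed)
  phi <- exp(-1 / (fs * tau))
  x <- as.numeric(stats::arima.sim(list(ar = phi), n,
                                   sd = sqrt(1 - phi^2)))
  velocity_series((seq_len(n) - 1) / fs, mean_u + sd_u * x,
                  sample_rate = fs)
}

# Numerical-integration oracle for the integral time scale of a series:
# direct lag-domain autocorrelation (stats::acf) integrated by trapezoid
# to its first zero crossing.
oracle_integral_scale <- function(series) {
  x <- series$u - mean(series$u)
  lag_max <- min(length(x) - 1L, as.integer(2 * series$sample_rate))
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = FALSE)$acf)
  iz <- which(rho <= 0)[1]
  if (is.na(iz)) iz <- length(rho)
  r <- rho[seq_len(iz)]
  mean(series$u) * sum((r[-1] + r[-length(r)]) / 2) / series$sample_rate
}

# A uniform straight-line velocity series (useful for cone-filter cases).
uniform_series <- function(u, v = 0, w = 0, n = 100, fs = 100) {
  velocity_series((seq_len(n) - 1) / fs, rep(u, n), rep(v, n), rep(w, n),
                  sample_rate = fs)
}

# Flow map whose fields are affine in (x, z): bilinear must be exact.
affine_map <- function(xs = seq(0, 1, 0.25), zs = seq(0, 1, 0.25),
                       a = 1, b = 2, c = 3, tunnel_speed = 6) {
  f <- outer(xs, zs, function(x, z) a + b * x + c * z)
  flow_map(xs, zs, speed = f, angle = f / 10, ti = f / 100, tunnel_speed)
}

grid_b_spec <- function(seed = 1, duration = 60)
  turbulence_spec(6, 0.126, 0.31, sample_rate = 1250, duration = duration,
                  seed = seed)

grid_a_spec <- function(seed = 1, duration = 60)
  turbulence_spec(6, 0.073, 0.22, sample_rate = 1250, duration = duration,
                  seed = seed)

# Plan with one 0.8 s and one 0.4 s hover separated by fast transits.
two_hover_plan <- function(noise = 0.3, seed = 7) {
  flight_plan(list(
    hover_segment(0.8, c(7.0, 0, 1.2), noise),
    transit_segment(to = c(7.4, 0.2, 1.4), speed = 1.5),
    hover_segment(0.4, c(7.4, 0.2, 1.4), noise),
    transit_segment(to = c(6.9, -0.2, 1.3), speed = 1.5),
    hover_segment(0.05, c(6.9, -0.2, 1.3), noise)
  ), seed = seed)
}
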