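# flow_characterization: cone filter, point statistics, spectra, scales

test_that("cone filter keeps the boundary, rejects beyond it", {
  mk <- function(angle_deg) {
    a <- angle_deg * pi / 180
    velocity_series(0:9 / 100, rep(cos(a) * 6, 10), numeric(10),
                    rep(sin(a) * 6, 10), sample_rate = 100)
  }
  expect_equal(cone_filter(mk(44))$n_rejected, 0)
  expect_equal(cone_filter(mk(45))$n_rejected, 0)   # boundary retained
  expect_error(cone_filter(mk(46)), class = "windhover_invalid") # all gone
  # mixed record: only the out-of-cone samples are dropped
  s <- velocity_series(0:3 / 100, c(6, 6, 0.1, 6), c(0, 0, 6, 0),
                       numeric(4), sample_rate = 100)
  f <- cone_filter(s)
  expect_equal(f$n_rejected, 1)
  expect_equal(length(f$series$u), 3)
})

test_that("cone filter is the identity within the cone, and idempotent", {
  s <- uniform_series(6)
  f <- cone_filter(s)
  expect_equal(f$n_rejected, 0)
  expect_identical(f$series, s)
  set.seed(1)
  noisy <- velocity_series(0:999 / 100, rnorm(1000, 6, 0.5),
                           rnorm(1000, 0, 4), rnorm(1000, 0, 4))
  f1 <- cone_filter(noisy)
  expect_gt(f1$n_rejected, 0)
  f2 <- cone_filter(f1$series)
  expect_equal(f2$n_rejected, 0)
  expect_equal(f2$series$u, f1$series$u)
})

test_that("point statistics match closed forms", {
  st <- point_statistics(uniform_series(6))
  expect_equal(st$pitch_angle, 0)
  expect_equal(st$turbulence_intensity, 0)
  expect_equal(st$mean_speed, 6)

  st10 <- point_statistics(uniform_series(6, 0, 6 * tan(10 * pi / 180)))
  expect_equal(st10$pitch_angle, 10)

  # sinusoid over whole periods: sd = amplitude / sqrt(2)
  fs <- 1000; t <- (0:(4 * fs - 1)) / fs
  u <- 6 + 0.6 * sqrt(2) * sin(2 * pi * t)
  st_sin <- point_statistics(velocity_series(t, u, sample_rate = fs))
  expect_equal(st_sin$turbulence_intensity, 0.100, tolerance = 0.001 / 0.1)

  # longitudinal TI unaffected by any zero-mean signal added to v
  v_sin <- velocity_series(t, u, 3 * sin(2 * pi * 5 * t), sample_rate = fs)
  expect_equal(point_statistics(v_sin)$turbulence_intensity,
               st_sin$turbulence_intensity)
  expect_error(point_statistics(uniform_series(-1)),
               class = "windhover_undefined_intensity")
})

test_that("Welch spectrum concentrates a sinusoid and satisfies Parseval", {
  fs <- 256; t <- (0:(64 * fs - 1)) / fs
  A <- 1.5; f0 <- 8
  s <- velocity_series(t, 6 + A * sin(2 * pi * f0 * t), sample_rate = fs)
  ps <- power_spectrum(s, segment_seconds = 4)
  tot <- sum(ps$density) * ps$frequency[1]
  expect_lt(abs(tot - A^2 / 2) / (A^2 / 2), 0.05)
  expect_equal(ps$frequency[which.max(ps$density)], f0)
  # white noise: flat density at sigma^2 / f_nyquist, slope ~ 0
  set.seed(2)
  wn <- velocity_series(t, 6 + rnorm(length(t)), sample_rate = fs)
  pw <- power_spectrum(wn, segment_seconds = 4)
  expect_lt(abs(sum(pw$density) * pw$frequency[1] - var(wn$u)) / var(wn$u),
            0.05)
  expect_lt(abs(mean(pw$density) - 1 / (fs / 2)) / (1 / (fs / 2)), 0.05)
  expect_lt(abs(spectral_slope(pw, c(2, 100))), 0.1)
  expect_error(power_spectrum(uniform_series(6, n = 50, fs = 100)),
               class = "windhover_invalid")
})

test_that("spectral slope is exact on an exact power law", {
  f <- seq(1, 100, by = 0.5)
  sp <- list(frequency = f, density = 3 * f^-2)
  expect_equal(spectral_slope(sp, c(2, 50)), -2)
  expect_error(spectral_slope(sp, c(50, 2)), class = "windhover_invalid")
  expect_error(spectral_slope(list(frequency = f, density = 3 * f^-2),
                              c(1, 2.4)),  # < 5 bins
               class = "windhover_invalid")
})

test_that("integral length scale: exponential-autocorrelation oracle", {
  tau <- 0.05; fs <- 1250
  s <- ar1_series(n = 120 * fs, fs = fs, mean_u = 6, sd_u = 0.5,
                  tau = tau, seed = 11)
  L <- integral_length_scale(s)
  expect_lt(abs(L - 6 * tau) / (6 * tau), 0.10)   # closed form: U * tau
  # agrees with the independent lag-domain numerical oracle
  expect_equal(L, oracle_integral_scale(s), tolerance = 1e-6)
})

test_that("integral length scale degenerate cases", {
  set.seed(3)
  wn <- velocity_series(0:(60 * 1250 - 1) / 1250, 6 + rnorm(60 * 1250),
                        sample_rate = 1250)
  expect_lt(integral_length_scale(wn), 0.01)
  expect_error(integral_length_scale(uniform_series(6)),
               class = "windhover_undefined_scale")
})
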