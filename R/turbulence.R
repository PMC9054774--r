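# Frequency-domain turbulence synthesis.
#
# A record of n samples is built by shaping complex Gaussian coefficients
# with the one-dimensional von Karman longitudinal spectrum
#   S(f) proportional to (1 + (1.339 * 2*pi*f*L/U)^2)^(-5/6),
# taking the inverse FFT and rescaling to the exact target mean and
# standard deviation. The constant 1.339 makes the zero-frequency limit of
# the normalised spectrum equal 4*L/U, so the integral time scale of the
# shaped process is L/U and (via Taylor's frozen-turbulence hypothesis) its
# integral length scale is L. At high frequency S ~ f^(-5/3), the
# Kolmogorov inertial-range decay.

von_karman_shape <- function(f, mean_speed, length_scale) {
  a <- 1.339 * 2 * pi * length_scale / mean_speed
  (1 + (a * f)^2)^(-5 / 6)
}

# One zero-mean Gaussian sample path with von Karman spectral shape,
# synthesised on the record's own frequency grid (resolution 1/duration).
vk_sample_path <- function(n, duration, mean_speed, length_scale) {
  nf <- n %/% 2L                       # positive-frequency bins
  f <- seq_len(nf) / duration
  amp <- sqrt(von_karman_shape(f, mean_speed, length_scale))
  spec <- complex(length.out = n)
  if (n %% 2L == 0L) {
    # bins 2..nf are conjugate pairs; bin nf+1 is the real Nyquist bin
    z <- complex(real = stats::rnorm(nf - 1L),
                 imaginary = stats::rnorm(nf - 1L)) * amp[-nf]
    spec[2:nf] <- z
    spec[nf + 1L] <- complex(real = stats::rnorm(1L)) * amp[nf]
    spec[n:(nf + 2L)] <- Conj(z)
  } else {
    z <- complex(real = stats::rnorm(nf),
                 imaginary = stats::rnorm(nf)) * amp
    spec[2:(nf + 1L)] <- z
    spec[n:(nf + 2L)] <- Conj(z[-nf])
  }
  Re(stats::fft(spec, inverse = TRUE))
}

rescale_exact <- function(x, target_mean, target_sd) {
  s <- stats::sd(x)
  if (s == 0) return(rep(target_mean, length(x)))
  (x - mean(x)) / s * target_sd + target_mean
}

#' Synthesise a turbulent wind record
#'
#' Generates a three-component velocity series whose longitudinal component
#' has exactly the requested sample mean and standard deviation and a von
#' Karman spectrum with inertial-range slope -5/3. Lateral and vertical
#' components are generated independently with the same standard deviation
#' and length scale (isotropy assumption) and zero mean.
#'
#' With `intensity_target = 0` the record is constant: `u` equals the mean
#' speed and `v`, `w` are identically zero.
#'
#' @param spec A [turbulence_spec()].
#' @return A [velocity_series()] of `duration * sample_rate` samples.
#' @examples
#' ts <- generate_turbulence(turbulence_spec(6, 0.126, 0.31, duration = 10))
#' sd(ts$u) / mean(ts$u)   # 0.126 exactly
#' @export
generate_turbulence <- function(spec) {
  if (!inherits(spec, "turbulence_spec"))
    abort_invalid("spec must be a turbulence_spec")
  n <- round(spec$sample_rate * spec$duration)
  if (n < 2L) abort_invalid("spec implies fewer than two samples")
  t <- (seq_len(n) - 1L) / spec$sample_rate
  sigma <- spec$intensity_target * spec$mean_speed
  if (sigma == 0) {
    return(velocity_series(t, u = rep(spec$mean_speed, n),
                           sample_rate = spec$sample_rate))
  }
  set.seed(spec$seed)
  u <- rescale_exact(
    vk_sample_path(n, spec$duration, spec$mean_speed,
                   spec$length_scale_target),
    spec$mean_speed, sigma)
  v <- rescale_exact(
    vk_sample_path(n, spec$duration, spec$mean_speed,
                   spec$length_scale_target), 0, sigma)
  w <- rescale_exact(
    vk_sample_path(n, spec$duration, spec$mean_speed,
                   spec$length_scale_target), 0, sigma)
  velocity_series(t, u, v, w, sample_rate = spec$sample_rate)
}
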