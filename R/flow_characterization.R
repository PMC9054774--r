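# Per-point statistics and spectral diagnostics for probe velocity records.

#' Reject samples outside the probe's cone of acceptance
#'
#' Pressure-probe anemometers resolve the velocity vector only within a
#' cone about the probe axis (+x); instantaneous samples deviating by more
#' than the half-angle (default +/- 45 degrees) are removed. The filter is
#' idempotent.
#'
#' @param series A [velocity_series()].
#' @param half_angle Cone half-angle, degrees (> 0); default 45.
#' @return List with `series` (the retained samples, time base preserved as
#'   the original stamps) and `n_rejected`.
#' @export
cone_filter <- function(series, half_angle = 45) {
  if (!inherits(series, "velocity_series"))
    abort_invalid("series must be a velocity_series")
  if (half_angle <= 0) abort_invalid("half_angle must be > 0")
  mag <- sqrt(series$u^2 + series$v^2 + series$w^2)
  # angle between the instantaneous vector and the +x probe axis
  ang <- ifelse(mag == 0, 0, acos(pmin(pmax(series$u / mag, -1), 1)) * 180 / pi)
  keep <- ang <= half_angle
  n_rej <- sum(!keep)
  if (!any(keep)) abort_invalid("all samples rejected by the cone filter")
  out <- if (n_rej == 0) series else
    structure(list(t = series$t[keep], u = series$u[keep],
                   v = series$v[keep], w = series$w[keep],
                   sample_rate = series$sample_rate),
              class = "velocity_series")
  list(series = out, n_rejected = n_rej)
}

#' Mean-flow statistics of a velocity record
#'
#' Computes the per-point quantities used to build flow maps: component
#' means, mean speed (norm of the mean vector), pitch angle
#' `atan2(mean w, mean u)` in degrees, and the longitudinal turbulence
#' intensity `sd(u) / mean(u)`.
#'
#' @param series A [velocity_series()] (typically a one-minute sample).
#' @param n_rejected Count of samples removed upstream (e.g. by
#'   [cone_filter()]), carried through for bookkeeping.
#' @return A one-row data frame of class `flow_sample_stats` with columns
#'   `mean_u`, `mean_v`, `mean_w`, `mean_speed`, `pitch_angle`,
#'   `turbulence_intensity`, `n_samples`, `n_rejected`.
#' @export
point_statistics <- function(series, n_rejected = 0L) {
  if (!inherits(series, "velocity_series"))
    abort_invalid("series must be a velocity_series")
  mu <- mean(series$u); mv <- mean(series$v); mw <- mean(series$w)
  if (mu <= 0)
    abort_invalid("mean longitudinal velocity <= 0: turbulence intensity undefined",
                  class = "windhover_undefined_intensity")
  n <- length(series$t)
  ti <- if (n > 1L) stats::sd(series$u) / mu else 0
  out <- data.frame(mean_u = mu, mean_v = mv, mean_w = mw,
                    mean_speed = sqrt(mu^2 + mv^2 + mw^2),
                    pitch_angle = atan2(mw, mu) * 180 / pi,
                    turbulence_intensity = ti,
                    n_samples = n, n_rejected = as.integer(n_rejected))
  class(out) <- c("flow_sample_stats", "data.frame")
  out
}

#' Welch power spectral density of one velocity component
#'
#' One-sided averaged modified periodogram (Hann window, 50 % overlap).
#' The integral of the density over frequency recovers the component
#' variance (Parseval consistency, within a few percent for long records).
#'
#' @param series A [velocity_series()].
#' @param component One of `"u"`, `"v"`, `"w"`.
#' @param segment_seconds Welch segment length in seconds; default 4.
#' @param overlap Fractional segment overlap; default 0.5.
#' @return An object of class `spectrum_estimate`: list with `frequency`
#'   (Hz, ascending, excludes 0), `density` ((m/s)^2/Hz), and estimator
#'   metadata (`segment_length`, `overlap`, `window`, `n_segments`).
#' @export
power_spectrum <- function(series, component = "u", segment_seconds = 4,
                           overlap = 0.5) {
  if (!inherits(series, "velocity_series"))
    abort_invalid("series must be a velocity_series")
  component <- match.arg(component, c("u", "v", "w"))
  x <- series[[component]]
  fs <- series$sample_rate
  nseg <- round(segment_seconds * fs)
  if (length(x) < 2L * nseg)
    abort_invalid("series shorter than two Welch segments")
  win <- hann_window(nseg)
  u2 <- sum(win^2)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * fs * u2)
  nf <- nseg %/% 2L
  dens <- 2 * p[2:(nf + 1L)]
  if (nseg %% 2L == 0L) dens[nf] <- dens[nf] / 2   # Nyquist bin is unpaired
  structure(list(frequency = seq_len(nf) * fs / nseg, density = dens,
                 segment_length = nseg, overlap = overlap, window = "hann",
                 n_segments = length(starts)),
            class = "spectrum_estimate")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Log-log spectral slope over a frequency band
#'
#' Least-squares slope of `log10(density)` against `log10(frequency)`
#' restricted to `[f_lo, f_hi]`. An inertial subrange of well-mixed
#' turbulence gives the Kolmogorov value -5/3.
#'
#' @param spectrum A `spectrum_estimate` (see [power_spectrum()]), or any
#'   list with `frequency` and `density`.
#' @param band Numeric length-2, `c(f_lo, f_hi)` in Hz, inside the spectrum
#'   support with at least 5 bins.
#' @return The fitted slope (dimensionless).
#' @export
spectral_slope <- function(spectrum, band) {
  if (band[1] >= band[2]) abort_invalid("band must satisfy f_lo < f_hi")
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2] &
    spectrum$density > 0
  if (sum(sel) < 5L)
    abort_invalid("fewer than 5 frequency bins in the requested band")
  lf <- log10(spectrum$frequency[sel])
  ld <- log10(spectrum$density[sel])
  unname(stats::coef(stats::lm.fit(cbind(1, lf), ld))[2])
}

#' Longitudinal integral length scale (Taylor's hypothesis)
#'
#' `L = mean(u) * integral of the u-fluctuation autocorrelation from lag 0
#' to its first zero crossing`, with the crossing located by linear
#' interpolation. Taylor's frozen-turbulence hypothesis converts the
#' integral time scale to a length by advecting at the mean speed.
#'
#' @param series A [velocity_series()].
#' @return Integral length scale in metres.
#' @export
integral_length_scale <- function(series) {
  if (!inherits(series, "velocity_series"))
    abort_invalid("series must be a velocity_series")
  mu <- mean(series$u)
  if (mu <= 0) abort_invalid("mean(u) must be > 0")
  x <- series$u - mu
  if (stats::sd(x) == 0)
    abort_invalid("zero variance: length scale undefined",
                  class = "windhover_undefined_scale")
  n <- length(x)
  nfft <- 2^ceiling(log2(2L * n))    # zero-padded FFT autocovariance
  ac <- Re(stats::fft(Mod(stats::fft(c(x, numeric(nfft - n))))^2,
                      inverse = TRUE))[seq_len(n)] / nfft
  rho <- ac / ac[1]
  dt <- 1 / series$sample_rate
  iz <- which(rho <= 0)[1]
  if (is.na(iz)) iz <- n
  r <- rho[seq_len(iz)]
  integ <- sum((r[-1] + r[-length(r)]) / 2) * dt
  if (r[iz] < 0) {
    # replace the last trapezoid with the triangle up to the crossing
    frac <- r[iz - 1L] / (r[iz - 1L] - r[iz])
    integ <- integ - (r[iz - 1L] + r[iz]) / 2 * dt +
      r[iz - 1L] * frac * dt / 2
  }
  mu * integ
}
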