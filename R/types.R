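#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout: x in metres downstream of the
# test-section inlet, y lateral from the tunnel centreline, z above the
# tunnel floor. Wind velocities in m/s; marker trajectories in mm.

abort_invalid <- function(msg, class = "windhover_invalid") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Uniformly sampled three-component velocity record at a point
#'
#' Container for a probe-style wind record: time base `t` (s), longitudinal
#' `u`, lateral `v` and vertical `w` components (m/s), and the sample rate.
#'
#' @param t Time stamps in seconds, strictly increasing and uniform.
#' @param u,v,w Velocity components in m/s, same length as `t`.
#' @param sample_rate Samples per second (Hz). Inferred from `t` if missing.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(t, u, v = numeric(length(u)),
                            w = numeric(length(u)), sample_rate = NULL) {
  n <- length(t)
  if (n < 1L) abort_invalid("velocity series must contain at least one sample")
  if (length(u) != n || length(v) != n || length(w) != n)
    abort_invalid("t, u, v, w must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(u)) ||
      !all(is.finite(v)) || !all(is.finite(w)))
    abort_invalid("velocity series contains non-finite values")
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) abort_invalid("time base must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      abort_invalid("time base not uniform (tolerance 1e-6 s)")
    if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  } else if (is.null(sample_rate)) {
    abort_invalid("sample_rate required for a single-sample series")
  }
  structure(list(t = as.numeric(t), u = as.numeric(u), v = as.numeric(v),
                 w = as.numeric(w), sample_rate = sample_rate),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$sample_rate, length(x$t) / x$sample_rate))
  cat(sprintf("  mean u/v/w [m/s]: %.3f / %.3f / %.3f\n",
              mean(x$u), mean(x$v), mean(x$w)))
  invisible(x)
}

#' @export
length.velocity_series <- function(x) length(x$t)

#' Target parameters for synthetic turbulence
#'
#' @param mean_speed Mean longitudinal speed, m/s (> 0).
#' @param intensity_target Longitudinal turbulence intensity sigma_u/U as a
#'   fraction in `[0, 1)`; 0 yields a constant record.
#' @param length_scale_target Longitudinal integral length scale, m.
#' @param sample_rate Sampling rate, Hz. Default 1250 (probe-class).
#' @param duration Record length, s. Default 60 (one-minute sample).
#' @param seed Integer seed; the record is reproducible from the spec alone.
#' @return An object of class `turbulence_spec`.
#' @export
turbulence_spec <- function(mean_speed, intensity_target,
                            length_scale_target, sample_rate = 1250,
                            duration = 60, seed = 1L) {
  if (!is.finite(mean_speed) || mean_speed <= 0)
    abort_invalid("mean_speed must be > 0")
  if (!is.finite(intensity_target) || intensity_target < 0 ||
      intensity_target >= 1)
    abort_invalid("intensity_target must lie in [0, 1)")
  if (!is.finite(length_scale_target) || length_scale_target <= 0)
    abort_invalid("length_scale_target must be > 0")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    abort_invalid("sample_rate must be > 0")
  if (!is.finite(duration) || duration <= 0)
    abort_invalid("duration must be > 0")
  structure(list(mean_speed = mean_speed,
                 intensity_target = intensity_target,
                 length_scale_target = length_scale_target,
                 sample_rate = sample_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "turbulence_spec")
}

#' Ramp geometry generating the orographic updraft
#'
#' Defaults are the facility's values: a 1.215 m surface inclined at 52 deg,
#' leading edge 7.14 m downstream of the test-section inlet and raised
#' 0.145 m above the floor so the boundary layer passes underneath.
#'
#' @param surface_length Ramp surface length, m.
#' @param incline Ramp incline, degrees in `[0, 90)`.
#' @param leading_edge_x Streamwise position of the leading edge, m.
#' @param floor_gap Height of the leading edge above the floor, m.
#' @return An object of class `ramp_geometry`.
#' @export
ramp_geometry <- function(surface_length = 1.215, incline = 52,
                          leading_edge_x = 7.14, floor_gap = 0.145) {
  if (incline < 0 || incline >= 90)
    abort_invalid("incline must lie in [0, 90) degrees")
  if (surface_length < 0 || leading_edge_x < 0 || floor_gap < 0)
    abort_invalid("ramp lengths must be >= 0")
  structure(list(surface_length = surface_length, incline = incline,
                 leading_edge_x = leading_edge_x, floor_gap = floor_gap),
            class = "ramp_geometry")
}

#' Flight volume monitored by the motion-capture system
#'
#' Default dimensions 1.35 x 1.5 x 0.75 m centred at (7.125, 0, 1.325) m.
#'
#' @param length,width,height Dimensions in m (> 0).
#' @param centroid_x,centroid_y,centroid_z Centroid coordinates in m.
#' @return An object of class `flight_volume`.
#' @export
flight_volume <- function(length = 1.35, width = 1.5, height = 0.75,
                          centroid_x = 7.125, centroid_y = 0,
                          centroid_z = 1.325) {
  if (length <= 0 || width <= 0 || height <= 0)
    abort_invalid("flight volume dimensions must be > 0")
  structure(list(length = length, width = width, height = height,
                 centroid_x = centroid_x, centroid_y = centroid_y,
                 centroid_z = centroid_z),
            class = "flight_volume")
}

#' @rdname flight_volume
#' @param volume A `flight_volume`.
#' @return `volume_bounds()`: list with `x`, `y`, `z` ranges (each length 2).
#' @export
volume_bounds <- function(volume) {
  list(x = volume$centroid_x + c(-0.5, 0.5) * volume$length,
       y = volume$centroid_y + c(-0.5, 0.5) * volume$width,
       z = volume$centroid_z + c(-0.5, 0.5) * volume$height)
}
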