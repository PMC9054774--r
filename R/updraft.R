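# Parametric model of the ramp-induced orographic updraft.
#
# The facility measures its updraft rather than modelling it, so any smooth
# deterministic field reproducing the measured envelope is acceptable here.
# The model below superimposes a uniform stream and a deflection kernel
# that decays exponentially with distance from the ramp surface:
#
#   angle(x, z) = min(k_a * incline, 45 deg) * exp(-d / lambda)
#   speed(x, z) = U * (1 + k_s * exp(-d / lambda))
#   ti(x, z)    = ti_freestream * (1 + k_t * exp(-d / lambda))
#
# where d is the distance from (x, z) to the ramp surface segment. Angles
# depend on geometry only (invariant to tunnel speed); speed scales
# linearly with tunnel speed; turbulence intensity peaks at the ramp
# surface, mimicking the developing boundary layer there. With the default
# geometry the defaults k_a = 0.8, k_s = 0.25, lambda = 0.4 m put ~6.6 deg
# through the flight-volume centroid, a 41.6 deg maximum at the surface and
# speeds within [6, 7.5] m/s at a 6 m/s tunnel speed.

ramp_surface_segment <- function(ramp) {
  p0 <- c(ramp$leading_edge_x, ramp$floor_gap)
  th <- ramp$incline * pi / 180
  p1 <- p0 + ramp$surface_length * c(cos(th), sin(th))
  list(p0 = p0, p1 = p1)
}

dist_to_segment <- function(x, z, seg) {
  d <- seg$p1 - seg$p0
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt((x - seg$p0[1])^2 + (z - seg$p0[2])^2))
  s <- ((x - seg$p0[1]) * d[1] + (z - seg$p0[2]) * d[2]) / len2
  s <- pmin(pmax(s, 0), 1)
  sqrt((x - (seg$p0[1] + s * d[1]))^2 + (z - (seg$p0[2] + s * d[2]))^2)
}

#' Evaluate the synthetic updraft model at arbitrary points
#'
#' Direct (grid-free) evaluation of the parametric ramp-updraft model; the
#' same closed form that [generate_updraft_field()] samples onto a lattice.
#'
#' @param ramp A [ramp_geometry()].
#' @param tunnel_speed Tunnel speed, m/s (> 0).
#' @param x,z Query coordinates, m (vectorised).
#' @param ti_freestream Freestream turbulence intensity (fraction);
#'   default 0.008, the smooth-flow baseline.
#' @param angle_gain,speed_gain,ti_gain,decay_length Model constants: peak
#'   deflection as a fraction of the incline, fractional speed-up at the
#'   surface, fractional turbulence boost at the surface, and the
#'   exponential decay length in m.
#' @return Data frame with columns `speed` (m/s), `angle` (degrees),
#'   `ti` (fraction).
#' @export
updraft_model_at <- function(ramp, tunnel_speed, x, z,
                             ti_freestream = 0.008, angle_gain = 0.8,
                             speed_gain = 0.25, ti_gain = 0.8,
                             decay_length = 0.4) {
  if (!inherits(ramp, "ramp_geometry"))
    abort_invalid("ramp must be a ramp_geometry")
  if (!is.finite(tunnel_speed) || tunnel_speed <= 0)
    abort_invalid("tunnel_speed must be > 0")
  seg <- ramp_surface_segment(ramp)
  d <- dist_to_segment(x, z, seg)
  kern <- exp(-d / decay_length)
  peak <- min(angle_gain * ramp$incline, 45)
  data.frame(speed = tunnel_speed * (1 + speed_gain * kern),
             angle = peak * kern,
             ti = ti_freestream * (1 + ti_gain * kern))
}

#' Generate a synthetic updraft flow map
#'
#' Samples the parametric ramp-updraft model onto a regular x-z lattice.
#' The pitch-angle field depends on geometry only and is therefore exactly
#' invariant to tunnel speed; the speed field scales linearly with tunnel
#' speed. With a zero-incline ramp every node has pitch angle 0.
#'
#' @inheritParams updraft_model_at
#' @param x_range,z_range Extents of the lattice, m (length-2 vectors).
#' @param spacing Lattice spacing, m; default 0.15 (the mapping convention).
#' @param cover Optional [flight_volume()] the lattice must cover in x-z;
#'   default the standard flight volume. Pass `NULL` to skip the check.
#' @param ... Passed to [updraft_model_at()] (model constants).
#' @return A [flow_map()].
#' @examples
#' fm <- generate_updraft_field(ramp_geometry(), 6)
#' interpolate_at(fm, 7.125, 1.325)   # flow at the flight-volume centroid
#' @export
generate_updraft_field <- function(ramp, tunnel_speed,
                                   x_range = c(6.45, 7.95),
                                   z_range = c(0.9, 1.8), spacing = 0.15,
                                   cover = flight_volume(), ...) {
  if (!is.finite(tunnel_speed) || tunnel_speed <= 0)
    abort_invalid("tunnel_speed must be > 0")
  if (!is.null(cover)) {
    b <- volume_bounds(cover)
    if (x_range[1] > b$x[1] + 1e-9 || x_range[2] < b$x[2] - 1e-9 ||
        z_range[1] > b$z[1] + 1e-9 || z_range[2] < b$z[2] - 1e-9)
      abort_invalid("grid does not cover the requested flight volume")
  }
  x <- seq(x_range[1], x_range[2], by = spacing)
  z <- seq(z_range[1], z_range[2], by = spacing)
  nodes <- expand.grid(x = x, z = z)
  fld <- updraft_model_at(ramp, tunnel_speed, nodes$x, nodes$z, ...)
  flow_map(x, z,
           speed = matrix(fld$speed, length(x), length(z)),
           angle = matrix(fld$angle, length(x), length(z)),
           ti = matrix(fld$ti, length(x), length(z)),
           tunnel_speed = tunnel_speed)
}
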