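# Regular x-z flow maps: assembly from point measurements, bilinear
# interpolation, and cross-speed comparison.

#' Regular x-z lattice of per-point flow statistics
#'
#' @param x,z Node coordinates in m, ascending with uniform spacing per axis
#'   (0.15 m grids are the facility convention, but any uniform spacing is
#'   accepted).
#' @param speed,angle,ti Matrices of dimension `length(x)` by `length(z)`:
#'   mean flow speed (m/s), pitch angle above horizontal (degrees) and
#'   longitudinal turbulence intensity (fraction).
#' @param tunnel_speed Nominal tunnel speed for this map, m/s (> 0).
#' @return An object of class `flow_map`.
#' @export
flow_map <- function(x, z, speed, angle, ti, tunnel_speed) {
  if (!is.finite(tunnel_speed) || tunnel_speed <= 0)
    abort_invalid("tunnel_speed must be > 0")
  if (is.unsorted(x, strictly = TRUE) || is.unsorted(z, strictly = TRUE))
    abort_invalid("grid coordinates must be strictly ascending")
  check_uniform <- function(v, name) {
    if (length(v) > 2L) {
      d <- diff(v)
      if (max(d) - min(d) > 1e-9)
        abort_invalid(sprintf("%s spacing is not uniform", name))
    }
  }
  check_uniform(x, "x"); check_uniform(z, "z")
  dm <- c(length(x), length(z))
  for (nm in c("speed", "angle", "ti")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), as.integer(dm)))
      abort_invalid(sprintf("%s must be a %d x %d matrix", nm, dm[1], dm[2]))
    if (!all(is.finite(m))) abort_invalid(sprintf("%s has non-finite values", nm))
  }
  structure(list(x = as.numeric(x), z = as.numeric(z), speed = speed,
                 angle = angle, ti = ti, tunnel_speed = tunnel_speed),
            class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("<flow_map> %d x %d nodes, x [%.2f, %.2f] m, z [%.2f, %.2f] m, tunnel %g m/s\n",
              length(x$x), length(x$z), min(x$x), max(x$x), min(x$z),
              max(x$z), x$tunnel_speed))
  cat(sprintf("  speed [%.2f, %.2f] m/s, angle [%.1f, %.1f] deg\n",
              min(x$speed), max(x$speed), min(x$angle), max(x$angle)))
  invisible(x)
}

# Snap measured coordinates (1 mm tolerance) onto their distinct values.
snap_axis <- function(v, tol = 1e-3) {
  u <- sort(unique(v))
  if (length(u) > 1L) {
    grp <- cumsum(c(TRUE, diff(u) > tol))
    u <- as.numeric(tapply(u, grp, mean))
  }
  idx <- vapply(v, function(p) which.min(abs(u - p)), integer(1))
  if (any(abs(u[idx] - v) > tol))
    abort_invalid("coordinate does not snap onto the lattice within 1 mm")
  list(values = u, index = idx)
}

#' Assemble a flow map from point measurements
#'
#' Point statistics measured on a complete rectangular x-z lattice (1 mm
#' coordinate tolerance) are arranged into a [flow_map()]. Duplicate or
#' missing nodes are errors; the missing-node error names the absent
#' coordinates.
#'
#' @param points Data frame with columns `x`, `z` (m) and the per-point
#'   statistics `speed` (m/s), `angle` (degrees), `ti` (fraction); the
#'   output columns of [point_statistics()] (`mean_speed`, `pitch_angle`,
#'   `turbulence_intensity`) are accepted as synonyms.
#' @param tunnel_speed Nominal tunnel speed, m/s.
#' @return A [flow_map()].
#' @export
assemble_map <- function(points, tunnel_speed) {
  points <- as.data.frame(points)
  rename <- c(mean_speed = "speed", pitch_angle = "angle",
              turbulence_intensity = "ti")
  for (nm in names(rename))
    if (nm %in% names(points) && !(rename[[nm]] %in% names(points)))
      names(points)[names(points) == nm] <- rename[[nm]]
  need <- c("x", "z", "speed", "angle", "ti")
  if (!all(need %in% names(points)))
    abort_invalid(paste("points must have columns:", paste(need, collapse = ", ")))
  if (nrow(points) < 1L) abort_invalid("no points supplied")
  sx <- snap_axis(points$x); sz <- snap_axis(points$z)
  nx <- length(sx$values); nz <- length(sz$values)
  lin <- (sz$index - 1L) * nx + sx$index
  if (anyDuplicated(lin)) {
    d <- lin[duplicated(lin)][1]
    abort_invalid(sprintf("duplicate node at (%.3f, %.3f)",
                          sx$values[(d - 1L) %% nx + 1L],
                          sz$values[(d - 1L) %/% nx + 1L]))
  }
  if (length(lin) != nx * nz) {
    miss <- setdiff(seq_len(nx * nz), lin)
    coords <- sprintf("(%.3f, %.3f)", sx$values[(miss - 1L) %% nx + 1L],
                      sz$values[(miss - 1L) %/% nx + 1L])
    abort_invalid(paste("missing lattice nodes:", paste(coords, collapse = " ")))
  }
  grid <- function(v) { m <- matrix(NA_real_, nx, nz); m[lin] <- v; m }
  flow_map(sx$values, sz$values, grid(points$speed), grid(points$angle),
           grid(points$ti), tunnel_speed)
}

#' Interpolate flow statistics at arbitrary positions
#'
#' Bilinear interpolation of each field of a flow map, exact at lattice
#' nodes. Queries outside the mapped hull raise an out-of-domain error:
#' no extrapolation is performed.
#'
#' @param map A [flow_map()].
#' @param x,z Query coordinates in m (vectorised, recycled to equal length).
#' @return Data frame with columns `speed`, `angle`, `ti`, one row per query.
#' @export
interpolate_at <- function(map, x, z) {
  if (!inherits(map, "flow_map")) abort_invalid("map must be a flow_map")
  n <- max(length(x), length(z))
  x <- rep_len(as.numeric(x), n); z <- rep_len(as.numeric(z), n)
  eps <- 1e-9
  if (any(x < min(map$x) - eps | x > max(map$x) + eps |
          z < min(map$z) - eps | z > max(map$z) + eps))
    abort_invalid("query outside the mapped hull (no extrapolation)",
                  class = "windhover_out_of_domain")
  ix <- pmin(pmax(findInterval(x, map$x), 1L), length(map$x) - 1L)
  iz <- pmin(pmax(findInterval(z, map$z), 1L), length(map$z) - 1L)
  if (length(map$x) == 1L) ix <- rep(1L, n)
  if (length(map$z) == 1L) iz <- rep(1L, n)
  fx <- if (length(map$x) > 1L)
    (x - map$x[ix]) / (map$x[ix + 1L] - map$x[ix]) else rep(0, n)
  fz <- if (length(map$z) > 1L)
    (z - map$z[iz]) / (map$z[iz + 1L] - map$z[iz]) else rep(0, n)
  fx <- pmin(pmax(fx, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  blend <- function(m) {
    i2 <- if (length(map$x) > 1L) ix + 1L else ix
    k2 <- if (length(map$z) > 1L) iz + 1L else iz
    m[cbind(ix, iz)] * (1 - fx) * (1 - fz) +
      m[cbind(i2, iz)] * fx * (1 - fz) +
      m[cbind(ix, k2)] * (1 - fx) * fz +
      m[cbind(i2, k2)] * fx * fz
  }
  data.frame(speed = blend(map$speed), angle = blend(map$angle),
             ti = blend(map$ti))
}

#' Compare two flow maps on the same lattice
#'
#' Speeds are normalised by each map's own tunnel speed before
#' differencing, so maps taken at different tunnel speeds are compared on
#' their dimensionless form. Returns the maxima over nodes.
#'
#' @param a,b [flow_map()] objects on identical lattices.
#' @return List with `max_speed_diff` (fraction of tunnel speed) and
#'   `max_angle_diff` (degrees).
#' @export
compare_maps <- function(a, b) {
  if (!inherits(a, "flow_map") || !inherits(b, "flow_map"))
    abort_invalid("both arguments must be flow_map objects")
  if (length(a$x) != length(b$x) || length(a$z) != length(b$z) ||
      max(abs(a$x - b$x)) > 1e-9 || max(abs(a$z - b$z)) > 1e-9)
    abort_invalid("maps are on different lattices")
  list(max_speed_diff = max(abs(a$speed / a$tunnel_speed -
                                  b$speed / b$tunnel_speed)),
       max_angle_diff = max(abs(a$angle - b$angle)))
}
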