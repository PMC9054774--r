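# Glide-envelope calculations: minimum glide angle from the maximum
# lift-to-drag ratio, and coverage of a bird's gliding envelope by a
# facility's speed / updraft-angle envelope.

#' Minimum glide angle from the maximum lift-to-drag ratio
#'
#' In equilibrium gliding the shallowest achievable glide path satisfies
#' `theta_min = cot^-1(L/D)`: drag steepens the glide, so a higher
#' lift-to-drag ratio flattens it. Strictly decreasing in `ld_max`,
#' 45 degrees at `ld_max = 1`, tending to 0 as `ld_max` grows.
#'
#' @param ld_max Maximum lift-to-drag ratio (> 0); vectorised.
#' @return Minimum glide angle in degrees.
#' @examples
#' min_glide_angle(10)    # 5.71 deg
#' @export
min_glide_angle <- function(ld_max) {
  if (any(!is.finite(ld_max)) || any(ld_max <= 0))
    abort_invalid("ld_max must be > 0")
  atan(1 / ld_max) * 180 / pi
}

#' Facility speed / updraft-angle envelope
#'
#' Defaults are the windhovering facility's published capability:
#' windspeeds 5 to 17 m/s, updraft angles 4.5 to 10 degrees through the
#' flight volume, turbulence intensity up to 15 %.
#'
#' @param speed_range Achievable windspeeds, m/s (length 2, ordered).
#' @param angle_range Achievable updraft angles, degrees (length 2, ordered).
#' @param ti_max Maximum turbulence intensity, fraction.
#' @return An object of class `facility_envelope`.
#' @export
facility_envelope <- function(speed_range = c(5, 17),
                              angle_range = c(4.5, 10), ti_max = 0.15) {
  if (speed_range[1] > speed_range[2] || angle_range[1] > angle_range[2])
    abort_invalid("envelope ranges must be ordered")
  structure(list(speed_range = speed_range, angle_range = angle_range,
                 ti_max = ti_max), class = "facility_envelope")
}

#' Does a facility envelope cover a glide-polar entry?
#'
#' Closed-interval containment: the entry's tested speed range must lie
#' within the facility's speed range, and the minimum glide angle derived
#' from `ld_max` must fall within the facility's updraft-angle range (so a
#' hanging glide at the shallowest angle can be sustained).
#'
#' @param entry One row of a glide polar table (see [load_polar_table()]),
#'   or any list with `v_min`, `v_max`, `ld_max`.
#' @param facility A [facility_envelope()].
#' @return List of flags: `speed_range_covered`, `theta_min_in_range`,
#'   `overall` (their conjunction), plus the derived `theta_min` (degrees).
#' @export
envelope_check <- function(entry, facility = facility_envelope()) {
  theta <- min_glide_angle(entry$ld_max)
  speed_ok <- entry$v_min >= facility$speed_range[1] &&
    entry$v_max <= facility$speed_range[2]
  angle_ok <- theta >= facility$angle_range[1] &&
    theta <= facility$angle_range[2]
  list(speed_range_covered = speed_ok, theta_min_in_range = angle_ok,
       overall = speed_ok && angle_ok, theta_min = theta)
}

#' Load a glide polar table
#'
#' Reads a CSV of per-species (or per-vehicle) glide data: columns `name`,
#' `v_min_ms`, `v_max_ms`, `v_min_sink_ms`, `v_theta_min_ms`, `ld_max`
#' (optional speeds may be blank). The minimum glide angle is always
#' recomputed from `ld_max`, never read from the file.
#'
#' The package ships a reference table of wind-tunnel glide tests on six
#' bird species and two bird-sized UAVs at
#' `system.file("extdata", "glide_polar_table1.csv", package = "windhover")`.
#'
#' @param source Path to the CSV file.
#' @return Data frame of class `glide_polar` with columns `name`, `v_min`,
#'   `v_max`, `v_min_sink`, `v_theta_min`, `ld_max`, `theta_min`.
#' @export
load_polar_table <- function(source) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    out <- data.frame(name = character(), v_min = numeric(),
                      v_max = numeric(), v_min_sink = numeric(),
                      v_theta_min = numeric(), ld_max = numeric(),
                      theta_min = numeric())
    class(out) <- c("glide_polar", "data.frame")
    return(out)
  }
  need <- c("name", "v_min_ms", "v_max_ms", "ld_max")
  if (!all(need %in% names(raw)))
    abort_invalid(paste("polar table must have columns:",
                        paste(need, collapse = ", ")))
  num <- function(col) {
    v <- raw[[col]]
    if (is.null(v)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(v))
  }
  out <- data.frame(name = as.character(raw$name), v_min = num("v_min_ms"),
                    v_max = num("v_max_ms"), v_min_sink = num("v_min_sink_ms"),
                    v_theta_min = num("v_theta_min_ms"), ld_max = num("ld_max"))
  for (i in seq_len(nrow(out))) {
    if (is.na(out$v_min[i]) || is.na(out$v_max[i]) || is.na(out$ld_max[i]) ||
        out$ld_max[i] <= 0 || out$v_min[i] > out$v_max[i])
      abort_invalid(sprintf("malformed polar table row %d ('%s')", i,
                            out$name[i]))
  }
  out$theta_min <- min_glide_angle(out$ld_max)
  class(out) <- c("glide_polar", "data.frame")
  out
}
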