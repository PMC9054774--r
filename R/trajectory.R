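# Synthetic motion-capture trajectories: hovers (station-keeping with
# isotropic sub-millimetre noise) separated by smooth transits.

#' Build a flight plan of hover and transit segments
#'
#' A flight plan is an ordered, time-contiguous list of segments. Hover
#' segments hold the head at an anchor position plus isotropic Gaussian
#' noise; transit segments move smoothly (cubic smoothstep, continuous
#' velocity, zero velocity at the joins) from the previous segment's
#' anchor to their own. The first segment must be a hover so the start
#' position is defined.
#'
#' @param segments List of segments from [hover_segment()] /
#'   [transit_segment()].
#' @param marker_offset Head-to-mantle offset vector, mm; the mantle marker
#'   is the head plus this constant offset (default 80 mm behind along -x).
#' @param seed Integer seed for the positional noise.
#' @return An object of class `flight_plan`.
#' @export
flight_plan <- function(segments, marker_offset = c(-80, 0, -20), seed = 1L) {
  if (length(segments) == 0L) abort_invalid("flight plan has no segments")
  kinds <- vapply(segments, `[[`, "", "kind")
  if (!all(kinds %in% c("hover", "transit")))
    abort_invalid("segments must be hover or transit")
  if (kinds[1] != "hover")
    abort_invalid("the first segment must be a hover (defines the start position)")
  structure(list(segments = segments,
                 marker_offset = as.numeric(marker_offset),
                 seed = as.integer(seed)),
            class = "flight_plan")
}

#' @rdname flight_plan
#' @param duration Segment duration, s (> 0).
#' @param anchor Anchor position `(x, y, z)` in metres (tunnel frame).
#' @param noise_sd Isotropic per-axis positional noise during the hover, mm.
#' @export
hover_segment <- function(duration, anchor, noise_sd = 0.3) {
  if (duration <= 0) abort_invalid("segment duration must be > 0")
  if (noise_sd < 0) abort_invalid("noise_sd must be >= 0")
  list(kind = "hover", duration = duration, anchor = as.numeric(anchor),
       noise_sd = noise_sd)
}

#' @rdname flight_plan
#' @param to Destination anchor `(x, y, z)` in metres.
#' @param speed Nominal transit speed, m/s; when `duration` is missing it is
#'   derived as `distance / speed`.
#' @export
transit_segment <- function(duration = NULL, to, speed = NULL) {
  if (is.null(duration)) {
    if (is.null(speed) || speed <= 0)
      abort_invalid("transit needs a duration or a positive speed")
    duration <- NA_real_   # resolved against the previous anchor at build time
  } else if (duration <= 0) abort_invalid("segment duration must be > 0")
  list(kind = "transit", duration = duration, anchor = as.numeric(to),
       speed = speed)
}

#' Ground-truth hover intervals of a flight plan
#'
#' @param plan A [flight_plan()] (durations must be resolved, i.e. the plan
#'   as used by [generate_flight_trajectory()]).
#' @return Data frame with `start`, `end` (s) and anchor columns
#'   `x_m`, `y_m`, `z_m`; one row per hover segment, sorted, non-overlapping.
#' @export
truth_record <- function(plan) {
  segs <- resolve_plan(plan)$segments
  t0 <- cumsum(c(0, vapply(segs, `[[`, 0, "duration")))
  hov <- which(vapply(segs, `[[`, "", "kind") == "hover")
  data.frame(start = t0[hov], end = t0[hov + 1L],
             x_m = vapply(segs[hov], function(s) s$anchor[1], 0),
             y_m = vapply(segs[hov], function(s) s$anchor[2], 0),
             z_m = vapply(segs[hov], function(s) s$anchor[3], 0))
}

# Fill in transit durations derived from distance / speed.
resolve_plan <- function(plan) {
  segs <- plan$segments
  prev <- segs[[1]]$anchor
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$kind == "transit" && is.na(s$duration)) {
      d <- sqrt(sum((s$anchor - prev)^2))
      segs[[i]]$duration <- max(d / s$speed, 1e-3)
    }
    prev <- s$anchor
  }
  plan$segments <- segs
  plan
}

#' Generate a synthetic marker trajectory with ground truth
#'
#' Renders a flight plan into head and mantle marker positions sampled at
#' `sample_rate`. During hovers the head is the anchor plus isotropic
#' Gaussian noise (the plan's per-segment noise sd, in mm); during
#' transits it follows a cubic smoothstep between anchors with no noise.
#' The mantle is the head plus the plan's fixed offset plus an independent
#' draw of the same noise. Positions are in mm (motion-capture convention);
#' anchors are given in m.
#'
#' @param plan A [flight_plan()].
#' @param sample_rate Capture rate, Hz; default 200.
#' @return List with `trajectory` (a `marker_trajectory`) and `truth`
#'   (data frame of planted hover intervals; see [truth_record()]).
#' @export
generate_flight_trajectory <- function(plan, sample_rate = 200) {
  if (!inherits(plan, "flight_plan")) abort_invalid("plan must be a flight_plan")
  if (sample_rate <= 0) abort_invalid("sample_rate must be > 0")
  plan <- resolve_plan(plan)
  segs <- plan$segments
  bounds <- cumsum(c(0, vapply(segs, `[[`, 0, "duration")))
  total <- bounds[length(bounds)]
  n <- floor(total * sample_rate) + 1L
  t <- (seq_len(n) - 1L) / sample_rate
  head <- matrix(NA_real_, n, 3L)
  seg_of <- pmin(findInterval(t, bounds, rightmost.closed = TRUE),
                 length(segs))
  prev_anchor <- segs[[1]]$anchor
  set.seed(plan$seed)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    idx <- which(seg_of == i)
    if (length(idx)) {
      if (s$kind == "hover") {
        pos <- matrix(s$anchor * 1000, length(idx), 3L, byrow = TRUE)
        if (s$noise_sd > 0)
          pos <- pos + matrix(stats::rnorm(3L * length(idx), 0, s$noise_sd),
                              ncol = 3L)
      } else {
        tau <- (t[idx] - bounds[i]) / s$duration
        sstep <- 3 * tau^2 - 2 * tau^3
        pos <- outer(1 - sstep, prev_anchor * 1000) +
          outer(sstep, s$anchor * 1000)
      }
      head[idx, ] <- pos
    }
    prev_anchor <- s$anchor
  }
  noise_sd <- vapply(segs[seg_of], function(s)
    if (s$kind == "hover") s$noise_sd else 0, 0)
  mantle <- head + matrix(plan$marker_offset, n, 3L, byrow = TRUE) +
    matrix(stats::rnorm(3L * n, 0, 1), ncol = 3L) * noise_sd
  traj <- marker_trajectory(t, list(head = head, mantle = mantle),
                            sample_rate)
  list(trajectory = traj, truth = truth_record(plan))
}

#' Uniformly sampled 3-D marker trajectory
#'
#' @param t Time stamps, s (uniform).
#' @param markers Named list of n-by-3 position matrices in mm; a `head`
#'   marker must be present.
#' @param sample_rate Capture rate, Hz.
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(t, markers, sample_rate = NULL) {
  n <- length(t)
  if (n < 1L) abort_invalid("empty trajectory")
  if (!"head" %in% names(markers))
    abort_invalid("head marker is required", class = "windhover_missing_marker")
  for (nm in names(markers)) {
    m <- markers[[nm]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      abort_invalid(sprintf("marker '%s' must be an n x 3 matrix", nm))
    if (!all(is.finite(m)))
      abort_invalid(sprintf("marker '%s' has non-finite coordinates", nm))
  }
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6)
      abort_invalid("trajectory time base must be uniform and increasing")
    if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  }
  structure(list(t = as.numeric(t), markers = markers,
                 sample_rate = sample_rate),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d samples @ %g Hz, markers: %s\n",
              length(x$t), x$sample_rate,
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

#' Draw a randomised flight plan inside a flight volume
#'
#' Convenience generator for cohort simulations: `n_hovers` hover anchors
#' uniform in the central portion of the flight volume, hover durations
#' uniform in `hover_range`, joined by transits at `transit_speed`.
#'
#' @param n_hovers Number of hover segments.
#' @param volume A [flight_volume()] providing the anchor region.
#' @param hover_range Hover duration range, s; default 0.6 to 2 s.
#' @param noise_sd Hover positional noise, mm; default 0.3.
#' @param transit_speed Transit speed between anchors, m/s; default 1.5.
#' @param seed Integer seed (drives anchors, durations and noise).
#' @return A [flight_plan()].
#' @export
random_flight_plan <- function(n_hovers, volume = flight_volume(),
                               hover_range = c(0.6, 2), noise_sd = 0.3,
                               transit_speed = 1.5, seed = 1L) {
  if (n_hovers < 1L) abort_invalid("need at least one hover")
  b <- volume_bounds(volume)
  set.seed(seed)
  shrink <- function(r) mean(r) + c(-0.4, 0.4) * diff(r)  # keep off the faces
  anchors <- cbind(stats::runif(n_hovers, shrink(b$x)[1], shrink(b$x)[2]),
                   stats::runif(n_hovers, shrink(b$y)[1], shrink(b$y)[2]),
                   stats::runif(n_hovers, shrink(b$z)[1], shrink(b$z)[2]))
  durs <- stats::runif(n_hovers, hover_range[1], hover_range[2])
  segs <- list()
  for (i in seq_len(n_hovers)) {
    if (i > 1L)
      segs <- c(segs, list(transit_segment(to = anchors[i, ],
                                           speed = transit_speed)))
    segs <- c(segs, list(hover_segment(durs[i], anchors[i, ], noise_sd)))
  }
  flight_plan(segs, seed = seed + 1L)
}
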