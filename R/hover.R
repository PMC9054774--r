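# Windhover epoch detection: regions where the head marker stays
# stationary (per-axis positional sd below threshold in every sliding
# window of the minimum duration) for at least 0.5 s.

# Rolling per-window standard deviation via cumulative sums. Columns are
# centred on their global mean first so the sums stay well conditioned for
# mm-scale coordinates.
rolling_sd <- function(m, w) {
  n <- nrow(m)
  nw <- n - w + 1L
  out <- matrix(NA_real_, nw, ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j] - mean(m[, j])
    c1 <- cumsum(c(0, x)); c2 <- cumsum(c(0, x^2))
    s1 <- c1[(w + 1L):(n + 1L)] - c1[seq_len(nw)]
    s2 <- c2[(w + 1L):(n + 1L)] - c2[seq_len(nw)]
    v <- (s2 - s1^2 / w) / (w - 1L)
    out[, j] <- sqrt(pmax(v, 0))
  }
  out
}

#' Detect windhover epochs in a marker trajectory
#'
#' Scans the head marker for maximal epochs in which every sliding window
#' of width `min_duration` (step one sample) has per-axis positional
#' standard deviation strictly below `std_threshold`. Overlapping
#' qualifying windows are merged; epochs separated by any non-qualifying
#' window remain distinct. Event statistics are recomputed over the merged
#' span.
#'
#' @param traj A [marker_trajectory()] with a `head` marker (mm).
#' @param min_duration Minimum stationary duration, s; default 0.5.
#' @param std_threshold Per-axis positional sd threshold, mm; default 1.
#' @return A data frame of class `hover_events`, one row per epoch, sorted
#'   by start time: `start`, `end`, `duration` (s), head centroid
#'   `cx`/`cy`/`cz` (mm), per-axis sd `sx`/`sy`/`sz` (mm), `spread` (RMS of
#'   the per-axis sds, mm), and mantle centroid `mantle_x`/`_y`/`_z` when a
#'   mantle marker is tracked. A trajectory shorter than `min_duration`
#'   yields zero rows.
#' @examples
#' plan <- flight_plan(list(hover_segment(1, c(7.1, 0, 1.3), noise_sd = 0)))
#' sim <- generate_flight_trajectory(plan)
#' detect_hovers(sim$trajectory)
#' @export
detect_hovers <- function(traj, min_duration = 0.5, std_threshold = 1.0) {
  if (!inherits(traj, "marker_trajectory"))
    abort_invalid("traj must be a marker_trajectory")
  if (min_duration <= 0 || std_threshold < 0)
    abort_invalid("min_duration must be > 0 and std_threshold >= 0")
  head <- traj$markers$head
  fs <- traj$sample_rate
  # a window of w samples spans (w - 1) / fs seconds
  w <- as.integer(floor(min_duration * fs + 1e-9)) + 1L
  n <- nrow(head)
  empty <- event_frame(0L, mantle = "mantle" %in% names(traj$markers))
  if (n < w) return(empty)
  sds <- rolling_sd(head, w)
  ok <- sds[, 1] < std_threshold & sds[, 2] < std_threshold &
    sds[, 3] < std_threshold
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ev <- event_frame(length(runs), mantle = "mantle" %in% names(traj$markers))
  for (k in seq_along(runs)) {
    i0 <- starts[runs[k]]                 # first qualifying window
    i1 <- ends[runs[k]] + w - 1L          # last sample of last window
    # Merged spans can pick up slow drift at their edges (each window
    # qualifies, the union need not). Enforce the event-level invariant,
    # per-axis sd < threshold, by shedding the worse edge sample; stops by
    # construction at a single window, which qualifies.
    while (i1 - i0 + 1L > w) {
      sd3 <- apply(head[i0:i1, , drop = FALSE], 2, stats::sd)
      ax <- which.max(sd3)
      if (sd3[ax] < std_threshold) break
      ctr <- mean(head[i0:i1, ax])
      if (abs(head[i1, ax] - ctr) >= abs(head[i0, ax] - ctr))
        i1 <- i1 - 1L else i0 <- i0 + 1L
    }
    span <- i0:i1
    ev$start[k] <- traj$t[i0]; ev$end[k] <- traj$t[i1]
    ev$duration[k] <- traj$t[i1] - traj$t[i0]
    ev[k, c("cx", "cy", "cz")] <- colMeans(head[span, , drop = FALSE])
    sd3 <- apply(head[span, , drop = FALSE], 2, stats::sd)
    ev[k, c("sx", "sy", "sz")] <- sd3
    ev$spread[k] <- sqrt(mean(sd3^2))
    if ("mantle" %in% names(traj$markers))
      ev[k, c("mantle_x", "mantle_y", "mantle_z")] <-
        colMeans(traj$markers$mantle[span, , drop = FALSE])
  }
  ev
}

event_frame <- function(n, mantle = TRUE) {
  cols <- c("start", "end", "duration", "cx", "cy", "cz",
            "sx", "sy", "sz", "spread")
  if (mantle) cols <- c(cols, "mantle_x", "mantle_y", "mantle_z")
  ev <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(cols),
                             dimnames = list(NULL, cols)))
  class(ev) <- c("hover_events", "data.frame")
  ev
}

#' Summarise a set of hover events
#'
#' @param events A `hover_events` data frame (possibly empty).
#' @return List with `count`, `total_duration` (s), `duration_min`,
#'   `duration_median`, `duration_max` (s; `NA` when empty),
#'   `max_spread` (mm) and `max_axis_sd` (mm).
#' @export
hover_summary <- function(events) {
  if (nrow(events) == 0L)
    return(list(count = 0L, total_duration = 0, duration_min = NA_real_,
                duration_median = NA_real_, duration_max = NA_real_,
                max_spread = NA_real_, max_axis_sd = NA_real_))
  list(count = nrow(events),
       total_duration = sum(events$duration),
       duration_min = min(events$duration),
       duration_median = stats::median(events$duration),
       duration_max = max(events$duration),
       max_spread = max(events$spread),
       max_axis_sd = max(events$sx, events$sy, events$sz))
}

#' Recall and precision of detected hovers against planted truth
#'
#' A truth interval counts as recovered when some event overlaps at least
#' `min_overlap` of its duration; an event counts as a true positive when
#' it overlaps some truth interval by at least `min_overlap` of the event
#' duration.
#'
#' @param events A `hover_events` data frame.
#' @param truth Data frame with `start`, `end` columns (s), e.g. from
#'   [generate_flight_trajectory()].
#' @param min_duration Only truth intervals at least this long are scored
#'   (shorter planted hovers are undetectable by design); default 0.
#' @param min_overlap Required overlap fraction; default 0.5.
#' @return List with `recall`, `precision`, `n_truth`, `n_events`.
#' @export
detection_metrics <- function(events, truth, min_duration = 0,
                              min_overlap = 0.5) {
  truth <- truth[truth$end - truth$start >= min_duration, , drop = FALSE]
  overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(events) == 0L) return(FALSE)
    any(overlap(truth$start[i], truth$end[i], events$start, events$end) >=
          min_overlap * (truth$end[i] - truth$start[i]))
  }, logical(1))
  hit_event <- vapply(seq_len(nrow(events)), function(i) {
    if (nrow(truth) == 0L) return(FALSE)
    any(overlap(events$start[i], events$end[i], truth$start, truth$end) >=
          min_overlap * (events$end[i] - events$start[i]))
  }, logical(1))
  list(recall = if (nrow(truth)) mean(hit_truth) else NA_real_,
       precision = if (nrow(events)) mean(hit_event) else NA_real_,
       n_truth = nrow(truth), n_events = nrow(events))
}
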