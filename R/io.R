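# File formats: TSV for time series and trajectories (motion-capture
# export style), CSV for derived tables, JSON for truth sidecars, config
# and reports. UTF-8, '.' decimal, fixed column order throughout.

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write / read a probe velocity series (TSV)
#'
#' Columns `t_s`, `u_ms`, `v_ms`, `w_ms`, tab-separated, 12 significant
#' digits (round trips at better than 1e-9 relative). Reading validates a
#' uniform time base (tolerance 1e-6 s) and rejects non-finite values; the
#' sample rate is inferred from the stamps.
#'
#' @param series A [velocity_series()].
#' @param path File path.
#' @return `read_probe_series()` returns a [velocity_series()];
#'   `write_probe_series()` returns `path` invisibly.
#' @export
write_probe_series <- function(series, path) {
  df <- data.frame(t_s = fmt_num(series$t), u_ms = fmt_num(series$u),
                   v_ms = fmt_num(series$v), w_ms = fmt_num(series$w))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_series
#' @export
read_probe_series <- function(path) {
  df <- tryCatch(utils::read.delim(path, check.names = FALSE),
                 error = function(e) abort_invalid(
                   sprintf("cannot read probe series '%s': %s", path,
                           conditionMessage(e)), class = "windhover_format"))
  need <- c("t_s", "u_ms", "v_ms", "w_ms")
  if (!identical(names(df)[seq_along(need)], need) || nrow(df) == 0L)
    abort_invalid("probe series must have columns t_s, u_ms, v_ms, w_ms and at least one row",
                  class = "windhover_format")
  if (anyNA(df)) abort_invalid("probe series contains missing values",
                               class = "windhover_format")
  tryCatch(velocity_series(df$t_s, df$u_ms, df$v_ms, df$w_ms),
           windhover_invalid = function(e) abort_invalid(
             paste("probe series format error:", conditionMessage(e)),
             class = "windhover_format"))
}

#' Write / read a marker trajectory (long TSV)
#'
#' Columns `t_s`, `marker`, `x_mm`, `y_mm`, `z_mm`; one row per marker per
#' time stamp.
#'
#' @param traj A [marker_trajectory()].
#' @param path File path.
#' @return `read_trajectory()` returns a [marker_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  rows <- do.call(rbind, lapply(names(traj$markers), function(nm) {
    m <- traj$markers[[nm]]
    data.frame(t_s = fmt_num(traj$t), marker = nm, x_mm = fmt_num(m[, 1]),
               y_mm = fmt_num(m[, 2]), z_mm = fmt_num(m[, 3]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("t_s", "marker", "x_mm", "y_mm", "z_mm")
  if (!identical(names(df), need) || nrow(df) == 0L)
    abort_invalid("trajectory must have columns t_s, marker, x_mm, y_mm, z_mm",
                  class = "windhover_format")
  markers <- lapply(split(df, df$marker), function(g) {
    g <- g[order(g$t_s), ]
    unname(as.matrix(g[, c("x_mm", "y_mm", "z_mm")]))
  })
  t <- sort(unique(df$t_s))
  marker_trajectory(t, markers)
}

#' Write / read a flow map (CSV with a tunnel-speed header)
#'
#' First line `# tunnel_speed_ms=<value>`, then columns `x_m`, `z_m`,
#' `speed_ms`, `angle_deg`, `ti_frac` in x-major order.
#'
#' @param map A [flow_map()].
#' @param path File path.
#' @return `read_flow_map()` returns a [flow_map()].
#' @export
write_flow_map <- function(map, path) {
  nodes <- expand.grid(x = map$x, z = map$z)
  df <- data.frame(x_m = fmt_num(nodes$x), z_m = fmt_num(nodes$z),
                   speed_ms = fmt_num(as.vector(map$speed)),
                   angle_deg = fmt_num(as.vector(map$angle)),
                   ti_frac = fmt_num(as.vector(map$ti)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tunnel_speed_ms=%s", fmt_num(map$tunnel_speed)), con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_map
#' @export
read_flow_map <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# tunnel_speed_ms=", first))
    abort_invalid("flow map file lacks the tunnel_speed header",
                  class = "windhover_format")
  ts <- as.numeric(sub("^# tunnel_speed_ms=", "", first))
  df <- utils::read.csv(path, skip = 1L)
  names(df) <- sub("_m$|_ms$|_deg$|_frac$", "", names(df))
  assemble_map(df, tunnel_speed = ts)
}

#' Write / read hover events (CSV)
#'
#' @param events A `hover_events` data frame.
#' @param path File path.
#' @return `read_hover_events()` returns the data frame.
#' @export
write_hover_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hover_events
#' @export
read_hover_events <- function(path) {
  ev <- utils::read.csv(path)
  class(ev) <- c("hover_events", "data.frame")
  ev
}

#' Write / read ground-truth hover intervals (JSON sidecar)
#'
#' @param truth Data frame from [truth_record()].
#' @param path File path.
#' @return `read_truth()` returns the data frame.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
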