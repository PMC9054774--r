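# Configuration and the end-to-end pipeline:
# simulate-wind -> characterize -> map-flow -> simulate-flight ->
# detect-hovers -> associate -> report.

#' Default pipeline configuration
#'
#' A nested list of every tunable parameter, with the facility's published
#' values as defaults where one exists. [read_config()] merges a JSON file
#' over these defaults and rejects unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    turbulence = list(mean_speed = 6, intensity_target = 0.126,
                      length_scale_target = 0.31, sample_rate = 1250,
                      duration = 60),
    ramp = list(surface_length = 1.215, incline = 52, leading_edge_x = 7.14,
                floor_gap = 0.145),
    flight_volume = list(length = 1.35, width = 1.5, height = 0.75,
                         centroid_x = 7.125, centroid_y = 0,
                         centroid_z = 1.325),
    map = list(tunnel_speed = 6, compare_speeds = c(5, 7),
               x_range = c(6.45, 7.95), z_range = c(0.9, 1.8),
               spacing = 0.15),
    flight = list(n_hovers = 8, hover_range = c(0.6, 2), noise_sd = 0.3,
                  transit_speed = 1.5, sample_rate = 200,
                  bird = "bird-1", condition = "grid B"),
    detector = list(min_duration = 0.5, std_threshold = 1.0,
                    marker = "mantle"),
    estimator = list(segment_seconds = 4, band = c(6, 60)),
    facility = list(speed_range = c(5, 17), angle_range = c(4.5, 10),
                    ti_max = 0.15)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste(path, nm, sep = ".") else nm
    if (!nm %in% names(base))
      abort_invalid(sprintf("unknown configuration key '%s'", key))
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path JSON file with any subset of the keys of
#'   [default_config()]; unknown keys are rejected.
#' @return Full configuration list (file values over defaults).
#' @export
read_config <- function(path) {
  if (is.null(path)) return(default_config())
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_config(), over)
}

#' Run the full synthetic pipeline
#'
#' Executes every stage against synthetic data: wind synthesis, flow
#' characterisation (turbulence intensity, spectral slope, integral length
#' scale), updraft mapping at the main and comparison tunnel speeds,
#' flight simulation, hover detection, flow association and cohort
#' statistics. All intermediate artifacts are written under `out_dir`, and
#' the run report (JSON) is deterministic given the configuration.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory; created if needed.
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("whrun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # simulate-wind + characterize
  spec <- stage("simulate-wind", do.call(turbulence_spec,
                                         c(config$turbulence,
                                           list(seed = config$seed))))
  wind <- stage("simulate-wind", generate_turbulence(spec))
  write_probe_series(wind, file.path(out_dir, "wind.tsv"))
  ch <- stage("characterize", {
    filt <- cone_filter(wind)
    st <- point_statistics(filt$series, filt$n_rejected)
    ps <- power_spectrum(wind, "u",
                         segment_seconds = config$estimator$segment_seconds)
    list(stats = st,
         slope = spectral_slope(ps, config$estimator$band),
         length_scale = integral_length_scale(wind))
  })

  # map-flow at the main speed and the comparison speeds
  ramp <- do.call(ramp_geometry, config$ramp)
  vol <- do.call(flight_volume, config$flight_volume)
  mk_map <- function(ts) generate_updraft_field(
    ramp, ts, x_range = config$map$x_range, z_range = config$map$z_range,
    spacing = config$map$spacing, cover = vol,
    ti_freestream = config$turbulence$intensity_target)
  map <- stage("map-flow", mk_map(config$map$tunnel_speed))
  write_flow_map(map, file.path(out_dir, "flow_map.csv"))
  cmp <- stage("map-flow", {
    ms <- lapply(config$map$compare_speeds, mk_map)
    compare_maps(ms[[1]], ms[[2]])
  })

  # simulate-flight -> detect-hovers
  plan <- stage("simulate-flight", random_flight_plan(
    config$flight$n_hovers, vol, hover_range = config$flight$hover_range,
    noise_sd = config$flight$noise_sd,
    transit_speed = config$flight$transit_speed, seed = config$seed))
  sim <- stage("simulate-flight",
               generate_flight_trajectory(plan, config$flight$sample_rate))
  write_trajectory(sim$trajectory, file.path(out_dir, "trajectory.tsv"))
  write_truth(sim$truth, file.path(out_dir, "truth.json"))
  events <- stage("detect-hovers", detect_hovers(
    sim$trajectory, config$detector$min_duration,
    config$detector$std_threshold))
  write_hover_events(events, file.path(out_dir, "hovers.csv"))

  # associate -> report
  warnings_log <- character()
  cohort <- NULL
  if (nrow(events) > 0L) {
    events$bird <- config$flight$bird
    events$condition <- config$flight$condition
    assoc <- stage("associate", associate_hovers(events, map,
                                                 config$detector$marker))
    utils::write.csv(as.data.frame(assoc),
                     file.path(out_dir, "associated.csv"), row.names = FALSE)
    cohort <- stage("associate", withCallingHandlers(
      cohort_statistics(assoc, by = c("bird", "condition")),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
  } else {
    warnings_log <- c(warnings_log, "no hover events detected: empty cohort")
  }
  metrics <- detection_metrics(events, sim$truth,
                               min_duration = config$detector$min_duration + 0.1)

  report <- list(
    package_version = as.character(utils::packageVersion("windhover")),
    seed = config$seed,
    parameters = config,
    wind = list(turbulence_intensity = ch$stats$turbulence_intensity,
                mean_speed = ch$stats$mean_speed,
                spectral_slope = ch$slope,
                integral_length_scale = ch$length_scale,
                n_rejected = ch$stats$n_rejected),
    map = list(angle_at_centroid = interpolate_at(map, vol$centroid_x,
                                                  vol$centroid_z)$angle,
               comparison = cmp),
    hovers = hover_summary(events),
    detection = metrics,
    cohort = if (is.null(cohort)) list() else as.data.frame(cohort),
    warnings = warnings_log
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
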