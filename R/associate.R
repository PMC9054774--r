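# Attach local flow conditions to detected hovers and compute cohort
# statistics per bird and flow condition.

#' Associate hover events with local flow conditions
#'
#' Projects each event's marker centroid (mm, converted to m) onto the
#' mapped x-z plane (the lateral coordinate is ignored: the map covers the
#' central plane only) and looks up speed, pitch angle and turbulence
#' intensity by bilinear interpolation. Centroids outside the mapped hull
#' are flagged `in_map = FALSE` and carry no flow values.
#'
#' @param events A `hover_events` data frame from [detect_hovers()].
#'   Extra metadata columns (e.g. `bird`, `condition`) are carried through.
#' @param map A [flow_map()].
#' @param marker Which centroid locates the hover: `"mantle"` (default;
#'   the marker plotted on flow maps) or `"head"`. Mantle falls back to
#'   head when no mantle columns are present.
#' @return Data frame of class `associated_hovers`: the event rows plus
#'   `x_m`, `z_m`, `in_map`, `speed`, `angle`, `ti`.
#' @export
associate_hovers <- function(events, map, marker = c("mantle", "head")) {
  marker <- match.arg(marker)
  if (!inherits(map, "flow_map")) abort_invalid("map must be a flow_map")
  ev <- as.data.frame(events)
  n <- nrow(ev)
  if (marker == "mantle" && !"mantle_x" %in% names(ev)) marker <- "head"
  if (marker == "mantle") {
    x <- ev$mantle_x / 1000; z <- ev$mantle_z / 1000
  } else {
    x <- ev$cx / 1000; z <- ev$cz / 1000
  }
  eps <- 1e-9
  inside <- x >= min(map$x) - eps & x <= max(map$x) + eps &
    z >= min(map$z) - eps & z <= max(map$z) + eps
  ev$x_m <- x; ev$z_m <- z; ev$in_map <- inside
  ev$speed <- NA_real_; ev$angle <- NA_real_; ev$ti <- NA_real_
  if (any(inside)) {
    f <- interpolate_at(map, x[inside], z[inside])
    ev$speed[inside] <- f$speed
    ev$angle[inside] <- f$angle
    ev$ti[inside] <- f$ti
  }
  class(ev) <- c("associated_hovers", "data.frame")
  ev
}

#' Per-group cohort statistics of associated hovers
#'
#' For each group (e.g. bird x flow condition) the arithmetic mean, sample
#' standard deviation (n - 1 denominator) and count of the local updraft
#' angle and speed over in-map hovers. Out-of-map hovers are excluded from
#' the statistics but counted in `n_excluded`; the accounting satisfies
#' `n + n_excluded = total events` per group. Groups with no in-map hover
#' are omitted with a warning. Standard deviations are `NA` for n = 1.
#'
#' @param associated An `associated_hovers` data frame.
#' @param by Character vector of grouping columns present in `associated`
#'   (default none: one overall group).
#' @return Data frame of class `cohort_stats` with the grouping columns and
#'   `n`, `n_excluded`, `mean_angle`, `sd_angle`, `mean_speed`, `sd_speed`.
#' @export
cohort_statistics <- function(associated, by = character()) {
  df <- as.data.frame(associated)
  if (length(by) && !all(by %in% names(df)))
    abort_invalid("grouping columns not present in the associated hovers")
  key <- if (length(by)) interaction(df[by], drop = TRUE, sep = " / ")
  else factor(rep("all", nrow(df)))
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    g <- df[key == lv, , drop = FALSE]
    inm <- g[g$in_map, , drop = FALSE]
    if (nrow(inm) == 0L) {
      warning(sprintf("group '%s' has no in-map hovers; omitted", lv))
      return(NULL)
    }
    sdn <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
    row <- data.frame(n = nrow(inm), n_excluded = nrow(g) - nrow(inm),
                      mean_angle = mean(inm$angle), sd_angle = sdn(inm$angle),
                      mean_speed = mean(inm$speed), sd_speed = sdn(inm$speed))
    if (length(by)) row <- cbind(g[1, by, drop = FALSE], row)
    row
  }))
  if (is.null(out)) abort_invalid("no group has an in-map hover")
  rownames(out) <- NULL
  class(out) <- c("cohort_stats", "data.frame")
  out
}

#' Render cohort statistics as report strings
#'
#' Formats each row as `"<mean> +/- <sd> deg s.d., n = <n>"`, the
#' conventional presentation of hover-cohort updraft angles.
#'
#' @param stats A `cohort_stats` data frame.
#' @param digits Decimal places; default 1.
#' @return Character vector, one string per group.
#' @export
format_cohort <- function(stats, digits = 1) {
  vapply(seq_len(nrow(stats)), function(i) {
    s <- stats[i, ]
    sd_part <- if (is.na(s$sd_angle)) "" else
      sprintf(" ± %s", round_away(s$sd_angle, digits))
    sprintf("%s%s deg s.d., n = %d",
            round_away(s$mean_angle, digits), sd_part, s$n)
  }, character(1))
}

# round half away from zero, returned as a fixed-decimal string
round_away <- function(x, digits = 1) {
  p <- 10^digits
  sprintf(paste0("%.", digits, "f"), sign(x) * floor(abs(x) * p + 0.5) / p)
}
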