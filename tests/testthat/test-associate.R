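# hover_flow_association

# hand-built events at chosen positions (metres), converted to mm
events_at <- function(xy) {
  n <- nrow(xy)
  ev <- data.frame(start = seq_len(n), end = seq_len(n) + 0.7,
                   duration = 0.7, cx = xy[, 1] * 1000, cy = 0,
                   cz = xy[, 2] * 1000, sx = 0.3, sy = 0.3, sz = 0.3,
                   spread = 0.3, mantle_x = xy[, 1] * 1000, mantle_y = 0,
                   mantle_z = xy[, 2] * 1000)
  class(ev) <- c("hover_events", "data.frame")
  ev
}

test_that("hover at a node takes node values; outside hull is flagged", {
  m <- affine_map(xs = seq(0, 1, 0.25), zs = seq(0, 1, 0.25))
  ev <- events_at(rbind(c(0.25, 0.5), c(2.0, 0.5)))
  assoc <- associate_hovers(ev, m)
  expect_true(assoc$in_map[1])
  expect_false(assoc$in_map[2])
  expect_equal(assoc$speed[1], 1 + 2 * 0.25 + 3 * 0.5)
  expect_true(is.na(assoc$speed[2]) && is.na(assoc$angle[2]))
})

test_that("marker choice: mantle default, head fallback and selection", {
  m <- affine_map()
  ev <- events_at(rbind(c(0.5, 0.5)))
  ev$mantle_x <- 600; ev$mantle_z <- 700     # mantle elsewhere
  by_mantle <- associate_hovers(ev, m)
  expect_equal(by_mantle$x_m, 0.6)
  by_head <- associate_hovers(ev, m, marker = "head")
  expect_equal(by_head$x_m, 0.5)
  ev2 <- events_at(rbind(c(0.5, 0.5)))
  ev2$mantle_x <- NULL; ev2$mantle_y <- NULL; ev2$mantle_z <- NULL
  expect_equal(associate_hovers(ev2, m)$x_m, 0.5)   # falls back to head
})

test_that("associated angles match direct evaluation of the model field", {
  ramp <- ramp_geometry()
  map <- generate_updraft_field(ramp, 6, spacing = 0.05)
  set.seed(6)
  xs <- runif(40, 6.6, 7.7); zs <- runif(40, 1.0, 1.7)
  assoc <- associate_hovers(events_at(cbind(xs, zs)), map)
  direct <- updraft_model_at(ramp, 6, xs, zs)
  # bilinear on a 5 cm lattice of a smooth exponential kernel: small
  # cell-level error bound
  expect_lt(max(abs(assoc$angle - direct$angle)), 0.2)
})

test_that("cohort statistics: closed forms, grouping, accounting", {
  m <- affine_map()
  ev <- events_at(rbind(c(0.2, 0.2), c(0.5, 0.5), c(0.8, 0.8), c(5, 5)))
  ev$bird <- c("k1", "k1", "k1", "k1")
  ev$condition <- "smooth"
  assoc <- associate_hovers(ev, m)
  assoc$angle[assoc$in_map] <- c(4, 5, 6)   # impose known angles
  st <- cohort_statistics(assoc, by = c("bird", "condition"))
  expect_equal(st$mean_angle, 5)
  expect_equal(st$sd_angle, 1)
  expect_equal(st$n, 3)
  expect_equal(st$n_excluded, 1)
  expect_equal(st$n + st$n_excluded, nrow(ev))

  # single hover: sd undefined
  one <- cohort_statistics(assoc[2, , drop = FALSE])
  expect_equal(one$n, 1)
  expect_true(is.na(one$sd_angle))

  # reordering commutes
  st2 <- cohort_statistics(assoc[c(3, 1, 4, 2), ], by = c("bird", "condition"))
  expect_equal(st2, st)

  # all hovers at one location: sd 0, mean = local value
  same <- associate_hovers(events_at(rbind(c(0.5, 0.5), c(0.5, 0.5))), m)
  st3 <- cohort_statistics(same)
  expect_equal(st3$sd_angle, 0)
  expect_equal(st3$mean_angle, (1 + 2 * 0.5 + 3 * 0.5) / 10)

  # group with zero in-map hovers is omitted with a warning
  out <- events_at(rbind(c(5, 5)))
  out$bird <- "k2"; out$condition <- "smooth"
  both <- rbind(assoc, associate_hovers(out, m))
  expect_warning(stw <- cohort_statistics(both, by = c("bird", "condition")),
                 "k2")
  expect_equal(nrow(stw), 1)
})

test_that("synthetic cohort recovers a planted angle distribution", {
  # angle field of the affine map is (1 + 2x + 3z)/10; choose positions on
  # the z = x diagonal so angle = (1 + 5x)/10 and invert for target angles
  m <- affine_map(xs = seq(0, 40, 2), zs = seq(0, 40, 2))
  set.seed(63)
  target <- 10 + rnorm(63, 0, 2)
  x <- (10 * target - 1) / 5
  assoc <- associate_hovers(events_at(cbind(x, x)), m)
  expect_true(all(assoc$in_map))
  st <- cohort_statistics(assoc)
  expect_equal(st$n, 63)
  expect_equal(st$mean_angle, mean(target), tolerance = 1e-9)
  expect_lt(abs(st$mean_angle - 10), 2 * 2 / sqrt(63))
})

test_that("format_cohort renders the conventional string", {
  df <- data.frame(n = 63L, n_excluded = 0L, mean_angle = 10.44,
                   sd_angle = 1.96, mean_speed = 6.6, sd_speed = 0.8)
  class(df) <- c("cohort_stats", "data.frame")
  expect_equal(format_cohort(df), "10.4 ± 2.0 deg s.d., n = 63")
  df$sd_angle <- NA_real_
  expect_equal(format_cohort(df), "10.4 deg s.d., n = 63")
})
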