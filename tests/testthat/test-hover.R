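# hover_detection

test_that("perfect 2 s stationarity yields exactly one full-span event", {
  plan <- flight_plan(list(hover_segment(2, c(7, 0, 1.3), 0)), seed = 1)
  sim <- generate_flight_trajectory(plan, 200)
  ev <- detect_hovers(sim$trajectory)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 0)
  expect_equal(ev$end, 2)
  expect_equal(ev$duration, 2)
  expect_equal(c(ev$sx, ev$sy, ev$sz), c(0, 0, 0))
  expect_equal(unname(unlist(ev[, c("cx", "cy", "cz")])), c(7000, 0, 1300))
})

test_that("straight transit at 1 m/s produces no events", {
  # uniform motion over a 0.5 s window spans 500 mm; sd = span/sqrt(12)
  fs <- 200; t <- 0:(3 * fs) / fs
  head <- cbind(1000 * t, 0 * t, 0 * t)
  traj <- marker_trajectory(t, list(head = head), fs)
  expect_equal(nrow(detect_hovers(traj)), 0)
})

test_that("detector honours its thresholds and invariants", {
  plan <- two_hover_plan(noise = 0.3, seed = 21)
  sim <- generate_flight_trajectory(plan, 200)
  ev <- detect_hovers(sim$trajectory, 0.5, 1.0)
  # only the 0.8 s planted hover qualifies (0.4 s and 0.05 s are too short)
  expect_equal(nrow(ev), 1)
  tr <- sim$truth[1, ]
  ov <- min(ev$end, tr$end) - max(ev$start, tr$start)
  expect_gte(ov / (tr$end - tr$start), 0.8)
  expect_gte(ev$duration, 0.5)
  expect_true(all(c(ev$sx, ev$sy, ev$sz) < 1.0))
})

test_that("trajectory shorter than min_duration yields empty, not error", {
  t <- 0:50 / 200   # 0.25 s
  traj <- marker_trajectory(t, list(head = matrix(0, 51, 3)), 200)
  ev <- detect_hovers(traj, 0.5, 1)
  expect_s3_class(ev, "hover_events")
  expect_equal(nrow(ev), 0)
})

test_that("determinism and threshold monotonicity", {
  plan <- random_flight_plan(5, seed = 31)
  sim <- generate_flight_trajectory(plan)
  e1 <- detect_hovers(sim$trajectory)
  expect_identical(e1, detect_hovers(sim$trajectory))
  covered <- function(lo, hi) {
    # every event of the stricter run lies inside an event of the looser run
    all(vapply(seq_len(nrow(lo)), function(i)
      any(hi$start <= lo$start[i] + 1e-9 & hi$end >= lo$end[i] - 1e-9),
      logical(1)))
  }
  e_loose_sd <- detect_hovers(sim$trajectory, 0.5, 2.0)
  expect_true(covered(e1, e_loose_sd))
  # lowering min_duration keeps a counterpart for every event (the
  # event-level sd trim may shave its edges, so test overlap, not nesting)
  e_short <- detect_hovers(sim$trajectory, 0.3, 1.0)
  overlaps <- vapply(seq_len(nrow(e1)), function(i)
    any(pmin(e1$end[i], e_short$end) - pmax(e1$start[i], e_short$start) >
          0.5 * e1$duration[i]), logical(1))
  expect_true(all(overlaps))
  expect_gte(nrow(e_short), nrow(e1))
})

test_that("closed loop: recall and precision 1.0 over 20 seeds", {
  for (s in 1:20) {
    plan <- random_flight_plan(4, hover_range = c(0.6, 2), noise_sd = 0.3,
                               transit_speed = 1.5, seed = s)
    sim <- generate_flight_trajectory(plan)
    ev <- detect_hovers(sim$trajectory)
    m <- detection_metrics(ev, sim$truth, min_duration = 0.6)
    expect_equal(m$recall, 1.0)
    expect_equal(m$precision, 1.0)
  }
})

test_that("missing head marker errors; hover_summary aggregates", {
  expect_error(marker_trajectory(0:10 / 10,
                                 list(mantle = matrix(0, 11, 3))),
               class = "windhover_missing_marker")
  empty <- detect_hovers(marker_trajectory(0:10 / 200,
                                           list(head = matrix(0, 11, 3)),
                                           200))
  expect_equal(hover_summary(empty)$count, 0)
  expect_equal(hover_summary(empty)$total_duration, 0)
  plan <- random_flight_plan(5, seed = 41)
  sim <- generate_flight_trajectory(plan)
  ev <- detect_hovers(sim$trajectory)
  sm <- hover_summary(ev)
  expect_equal(sm$count, nrow(ev))
  expect_equal(sm$total_duration, sum(ev$duration))
  expect_lt(sm$max_axis_sd, 1)
  expect_equal(sm$max_spread, max(ev$spread))
})
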