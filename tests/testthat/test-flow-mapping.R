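# flow_mapping: assembly, bilinear interpolation, map comparison

make_points <- function(xs, zs, f = function(x, z) x + 10 * z) {
  g <- expand.grid(x = xs, z = zs)
  data.frame(x = g$x, z = g$z, speed = f(g$x, g$z),
             angle = f(g$x, g$z) / 10, ti = f(g$x, g$z) / 100)
}

test_that("assemble_map builds grids and round-trips node values", {
  p1 <- make_points(0.3, 0.6)
  m1 <- assemble_map(p1, 6)
  expect_equal(dim(m1$speed), c(1L, 1L))
  expect_equal(interpolate_at(m1, 0.3, 0.6)$speed, p1$speed[1])

  p <- make_points(c(0, 0.15), c(0, 0.15))
  m <- assemble_map(p, 6)
  for (i in seq_len(nrow(p)))
    expect_equal(interpolate_at(m, p$x[i], p$z[i])$speed, p$speed[i])
  # point_statistics column names are accepted directly
  p2 <- data.frame(x = p$x, z = p$z, mean_speed = p$speed,
                   pitch_angle = p$angle, turbulence_intensity = p$ti)
  expect_equal(assemble_map(p2, 6)$speed, m$speed)
})

test_that("duplicate and missing nodes are rejected, with coordinates", {
  p <- make_points(c(0, 0.15), c(0, 0.15))
  expect_error(assemble_map(rbind(p, p[1, ]), 6), "duplicate",
               class = "windhover_invalid")
  expect_error(assemble_map(p[-2, ], 6), "missing lattice nodes.*0\\.15",
               class = "windhover_invalid")
  # coordinates snap within 1 mm, fail beyond it
  p_jit <- p; p_jit$x[2] <- p_jit$x[2] + 5e-4
  expect_silent(assemble_map(p_jit, 6))
})

test_that("bilinear interpolation is exact on affine fields", {
  m <- affine_map(a = 1, b = 2, c = 3)
  set.seed(4)
  xq <- runif(50); zq <- runif(50)
  got <- interpolate_at(m, xq, zq)
  expect_equal(got$speed, 1 + 2 * xq + 3 * zq, tolerance = 1e-12)
})

test_that("interpolation matches the brute-force oracle to 1e-12", {
  set.seed(5)
  xs <- seq(0, 1.5, 0.15); zs <- seq(0, 0.9, 0.15)
  sp <- matrix(runif(length(xs) * length(zs), 4, 8), length(xs))
  an <- matrix(runif(length(xs) * length(zs), 0, 40), length(xs))
  ti <- matrix(runif(length(xs) * length(zs), 0, 0.2), length(xs))
  m <- flow_map(xs, zs, sp, an, ti, 6)
  xq <- runif(100, 0, 1.5); zq <- runif(100, 0, 0.9)
  got <- interpolate_at(m, xq, zq)
  for (i in 1:100) {
    expect_equal(got$speed[i], oracle_bilinear(xs, zs, sp, xq[i], zq[i]),
                 tolerance = 1e-12)
    expect_equal(got$angle[i], oracle_bilinear(xs, zs, an, xq[i], zq[i]),
                 tolerance = 1e-12)
  }
  # monotone: bounded by the enclosing cell corners
  for (i in 1:100) {
    ix <- findInterval(xq[i], xs); iz <- findInterval(zq[i], zs)
    corners <- sp[ix:(ix + 1), iz:(iz + 1)]
    expect_gte(got$speed[i], min(corners) - 1e-12)
    expect_lte(got$speed[i], max(corners) + 1e-12)
  }
})

test_that("queries outside the hull error (no extrapolation)", {
  m <- affine_map()
  expect_error(interpolate_at(m, -0.1, 0.5),
               class = "windhover_out_of_domain")
  expect_error(interpolate_at(m, 0.5, 1.2),
               class = "windhover_out_of_domain")
})

test_that("compare_maps normalises by tunnel speed", {
  a <- affine_map(tunnel_speed = 6)
  self <- compare_maps(a, a)
  expect_equal(self$max_speed_diff, 0)
  expect_equal(self$max_angle_diff, 0)

  b <- a; b$speed <- a$speed * 1.1
  d <- compare_maps(a, b)
  expect_equal(d$max_speed_diff, 0.1 * max(a$speed) / 6)
  expect_equal(d$max_angle_diff, 0)
  # symmetry
  expect_equal(compare_maps(b, a)$max_speed_diff, d$max_speed_diff)
  expect_error(compare_maps(a, affine_map(xs = seq(0, 1, 0.5))),
               class = "windhover_invalid")
})

test_that("synthetic updraft maps at 5 and 7 m/s agree after normalisation", {
  a <- generate_updraft_field(ramp_geometry(), 5)
  b <- generate_updraft_field(ramp_geometry(), 7)
  d <- compare_maps(a, b)
  expect_lt(d$max_speed_diff, 1e-12)   # well inside the facility's 2 %
  expect_lt(d$max_angle_diff, 1e-12)   # and 0.5 deg repeatability bounds
})
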