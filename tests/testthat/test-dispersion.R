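test_that("lognormal size bins partition mass at equal quantiles", {
  b1 <- size_bins(size_distribution(gsd = 1))
  expect_equal(b1$diameter_um, 10)
  expect_equal(b1$mass_fraction, 1)

  b5 <- size_bins(size_distribution(10, 4, 5))
  expect_equal(b5$mass_fraction, rep(0.2, 5))
  expect_equal(b5$diameter_um[3], 10)  # median of the lognormal is the GMD
  expect_false(is.unsorted(b5$diameter_um))

  for (nb in c(2, 3, 7)) {
    b <- size_bins(size_distribution(10, 2.5, nb))
    expect_equal(sum(b$mass_fraction), 1, tolerance = 1e-12)
  }
  expect_error(size_distribution(gsd = 0.5), "GSD")
})

test_that("Stokes settling follows the d-squared law", {
  expect_equal(settling_velocity(10, 1500, 1.81e-5), 4.52e-3, tolerance = 0.02)
  expect_equal(settling_velocity(0), 0)
  expect_equal(settling_velocity(20) / settling_velocity(10), 4,
               tolerance = 1e-12)
  expect_error(settling_velocity(150), "Stokes")
})

test_that("puffs advect with the wind and settle per size bin", {
  src <- point_source(0, 0, height = 50)
  grid <- dispersion_grid(-500, -500, 50, 21, 21)

  # zero wind: horizontal centroid fixed, z strictly decreasing
  run0 <- run_dispersion(src, size_distribution(10, 1, 1), function(t) c(0, 0),
                         grid, duration_s = 100, release_interval_s = 1000,
                         dt = 10)
  expect_equal(run0$puffs$x, 0)
  expect_equal(run0$puffs$y, 0)
  expect_lt(run0$puffs$z[1, 1], 50)

  # wind (1, 0) for 100 s displaces the centroid by (100, 0)
  run1 <- run_dispersion(src, size_distribution(10, 1, 1), function(t) c(1, 0),
                         grid, duration_s = 100, release_interval_s = 1000,
                         dt = 10)
  expect_equal(run1$puffs$x, 100)
  expect_equal(run1$puffs$y, 0)
})

test_that("mass is conserved between air and ground at every step", {
  src <- point_source(0, 0)
  grid <- dispersion_grid(-1000, -1000, 100, 21, 21)
  wind <- function(t) c(2, -1)
  bins <- size_bins(size_distribution())
  run <- run_dispersion(src, size_distribution(), wind, grid,
                        duration_s = 400, release_interval_s = 20, dt = 10)
  expect_lt(run$mass_error, 1e-9)
  expect_gt(run$deposited, 0)     # coarse bins reach the ground
  expect_gt(run$airborne, 0)      # fine bins stay aloft
  expect_equal(run$emitted, src$emission_g_s * 20 * 20)
})

test_that("steady wind keeps the plume on the wind axis", {
  src <- point_source(0, 0, height = 100)
  grid <- dispersion_grid(-100, -100, 100, 11, 11)
  run <- run_dispersion(src, size_distribution(10, 1, 1), function(t) c(3, 4),
                        grid, duration_s = 300, release_interval_s = 1e6,
                        dt = 10)
  disp <- c(run$puffs$x[1], run$puffs$y[1])
  angle <- acos(sum(disp * c(3, 4)) / (sqrt(sum(disp^2)) * 5))
  expect_lt(abs(angle), 1e-6)
  expect_equal(sqrt(sum(disp^2)), 5 * 300)
})

test_that("a puff kernel integrates to its airborne mass", {
  # single high puff, no settling loss; Riemann sum over a fine 3-D grid
  src <- point_source(0, 0, height = 60)
  coarse <- dispersion_grid(-200, -200, 20, 21, 21)
  run <- run_dispersion(src, size_distribution(10, 1, 1), function(t) c(1, 1),
                        coarse, duration_s = 60, release_interval_s = 1e6,
                        dt = 10)
  m_air <- sum(run$puffs$mass)
  sh <- run$puffs$sigma_h0 + 0.1 * run$puffs$travel
  # fine grid spanning +-6 sigma horizontally and the full column vertically
  dx <- sh / 4
  xs <- seq(run$puffs$x[1] - 6 * sh, run$puffs$x[1] + 6 * sh, by = dx)
  zs <- seq(0.5, 150, by = 1)
  total <- 0
  for (z in zs) {
    g <- dispersion_grid(min(xs), min(xs), dx, length(xs), length(xs),
                         receptor_height = z)
    total <- total + sum(concentration_field(run$puffs, g)) * dx * dx * 1
  }
  expect_equal(total, m_air, tolerance = 0.01)
})

test_that("field peaks at the puff centroid and reverses with the wind", {
  src <- point_source(0, 0, height = 1.5)
  grid <- dispersion_grid(-1000, -2600, 50, 41, 61, receptor_height = 1.5)
  south <- run_dispersion(src, size_distribution(10, 1, 1),
                          function(t) c(0, -5), grid, duration_s = 200,
                          release_interval_s = 1e6, dt = 10)
  f <- south$fields[[length(south$fields)]]
  peak <- which(f == max(f), arr.ind = TRUE)[1, ]
  expect_equal(grid$xs[peak["row"]], south$puffs$x[1], tolerance = 50)
  expect_equal(grid$ys[peak["col"]], south$puffs$y[1], tolerance = 50)

  # mirrored wind mirrors the displacement about the source
  north <- run_dispersion(src, size_distribution(10, 1, 1),
                          function(t) c(0, 5), grid, duration_s = 200,
                          release_interval_s = 1e6, dt = 10)
  expect_equal(north$puffs$y[1], -south$puffs$y[1])

  # Q = 0: all fields are zero
  q0 <- run_dispersion(point_source(0, 0, emission_g_s = 0),
                       size_distribution(), function(t) c(0, -5), grid,
                       duration_s = 200, release_interval_s = 50, dt = 10)
  expect_true(all(vapply(q0$fields, max, 1) == 0))
})

test_that("deposited fraction grows with the size-distribution spread", {
  src <- point_source(0, 0)
  grid <- dispersion_grid(-100, -100, 100, 11, 11)
  dep_frac <- vapply(c(1.5, 2.5, 4), function(gsd) {
    run <- run_dispersion(src, size_distribution(10, gsd, 5),
                          function(t) c(0, 0), grid, duration_s = 100,
                          release_interval_s = 1e6, dt = 10)
    run$deposited / run$emitted
  }, 1)
  expect_true(all(diff(dep_frac) >= 0))
  expect_gt(dep_frac[3], dep_frac[1])
})

test_that("a receptor 2.5 km downwind sees a transport-delayed signal", {
  src <- point_source(0, 0, height = 50)
  grid <- dispersion_grid(-500, -3000, 50, 21, 61, receptor_height = 1.5)
  run <- run_dispersion(src, size_distribution(10, 1, 1),
                        function(t) c(0, -5), grid, duration_s = 800,
                        release_interval_s = 1e6, dt = 10,
                        output_every_s = 10)
  rs <- receptor_series(run, 0, -2500)
  # plume centroid needs 2500 m / 5 m/s = 500 s to reach the receptor
  peak_t <- rs$time_s[which.max(rs$concentration_g_m3)]
  expect_lte(abs(peak_t - 2500 / 5), 10)  # within one time step
  # negligible signal long before arrival
  early <- rs$concentration_g_m3[rs$time_s <= 300]
  expect_true(all(early < 1e-6 * max(rs$concentration_g_m3)))
})
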