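test_that("counts convert to concentrations by sampled volume", {
  expect_equal(round(counts_to_concentration(20, 2.8, 1)), 7143)
  expect_equal(counts_to_concentration(0, 2.8, 1), 0)
  expect_equal(counts_to_concentration(84, 10, 60), 140)
  expect_error(counts_to_concentration(5, 0, 1), "positive")
  expect_error(counts_to_concentration(5, 2.8, 0), "positive")
  expect_error(counts_to_concentration(-1, 2.8, 1), ">= 0")

  # round trip: concentration times volume recovers the count
  set.seed(4)
  counts <- rpois(50, 8)
  conc <- counts_to_concentration(counts, 2.8, 1)
  expect_equal(conc * 2.8 * 1 / 1000, counts, tolerance = 1e-9)
})

test_that("hourly aggregation is the volume-weighted minute mean", {
  s <- concentration_series(0:59, rep(42, 60))
  expect_equal(aggregate_hourly(s)$values, 42)

  v <- c(7143, rep(0, 59))
  expect_equal(aggregate_hourly(concentration_series(0:59, v))$values,
               7143 / 60, tolerance = 1e-12)

  empty <- concentration_series(numeric(0), numeric(0))
  expect_length(aggregate_hourly(empty)$values, 0)

  # partial trailing hour dropped with a message
  s90 <- concentration_series(0:89, rep(1, 90))
  expect_message(h <- aggregate_hourly(s90), "partial")
  expect_length(h$values, 1)
})

test_that("scaling factor is the ratio of calibration-bin sums", {
  expect_equal(compute_scaling_factor(c(5, 6, 7), c(5, 6, 7)), 1.0)
  expect_equal(compute_scaling_factor(c(10, 20, 30), c(2, 4, 6)), 5.0)
  expect_error(compute_scaling_factor(c(1, 2), c(0, 0)), "undefined")

  # exact k-recovery for any positive series
  set.seed(8)
  for (k in c(0.5, 1, 4.53, 12)) {
    x <- runif(24, 1, 100)
    expect_equal(compute_scaling_factor(k * x, x), k)
  }

  # calibration restricted to chosen bins only
  ref <- c(10, 10, 100, 100)
  dev <- c(5, 5, 1, 1)
  expect_equal(compute_scaling_factor(ref, dev, calibration_bins = 1:2), 2)
})

test_that("linear scaling applies and inverts cleanly", {
  s <- concentration_series(0:2, c(1, 2, 3))
  expect_equal(apply_scaling(s, 1)$values, s$values)
  expect_equal(apply_scaling(s, 2)$values, c(2, 4, 6))
  expect_equal(apply_scaling(apply_scaling(s, 4.53), 1 / 4.53)$values,
               s$values, tolerance = 1e-12)
  expect_error(apply_scaling(s, 0), "positive")
})

test_that("pearson_r matches the product-moment oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(as.numeric(pearson_r(x, 2 * x)), 1.0)
  expect_equal(as.numeric(pearson_r(x, -x)), -1.0)
  expect_equal(as.numeric(pearson_r(c(1, 2, 3), c(1, 2, 4))), 0.9820,
               tolerance = 1e-4)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")

  # invariant to positive affine rescaling
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(as.numeric(pearson_r(2 * a + 7, b)),
               as.numeric(pearson_r(a, b)), tolerance = 1e-12)
})

test_that("calibration enforces disjoint validation bins", {
  set.seed(3)
  dev <- runif(48, 1, 50)
  ref <- 4.53 * dev * exp(rnorm(48, 0, 0.05))
  cal <- calibrate_concentrations(ref, dev, calibration_bins = 1:12)
  expect_equal(cal$n_validation, 36)
  expect_gt(cal$pearson_r, 0.9)
  expect_error(calibrate_concentrations(ref, dev, calibration_bins = 1:12,
                                        validation_bins = 10:20), "disjoint")
})

test_that("mass concentration follows the spherical-granule model", {
  m <- mass_model()  # 1.5 g/cm3, 10 um spheres
  expect_equal(signif(mass_concentration(10000, m), 1), 0.008)
  expect_equal(mass_concentration(10000, m), 7.854e-3, tolerance = 1e-4)
  expect_equal(mass_concentration(0, m), 0)
  expect_equal(mass_concentration(1, m), 7.854e-7, tolerance = 1e-4)

  # linear in number concentration, cubic in diameter
  expect_equal(mass_concentration(300, m), 300 * mass_concentration(1, m))
  for (d in c(5, 10, 20)) {
    md <- mass_model(diameter_um = d)
    expect_equal(mass_concentration(1, md),
                 mass_concentration(1, mass_model(diameter_um = 1)) * d^3,
                 tolerance = 1e-12)
  }
})

test_that("episode detection finds maximal above-threshold runs", {
  s <- concentration_series(0:6, c(0, 0, 5, 7, 6, 0, 0))
  ep <- detect_episodes(s, 1)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_min, 2)
  expect_equal(ep$duration_min, 3)
  expect_equal(ep$peak, 7)

  expect_equal(nrow(detect_episodes(rep(0, 10), 1)), 0)

  all_above <- detect_episodes(rep(9, 15), 1)
  expect_equal(all_above$duration_min, 15)

  # episode durations partition the above-threshold minutes exactly
  set.seed(6)
  for (i in 1:10) {
    v <- rpois(200, 1) * rbinom(200, 1, 0.3)
    th <- sample(0:2, 1)
    ep <- detect_episodes(v, th)
    expect_equal(sum(ep$duration_min), sum(v > th))
    if (nrow(ep) > 1)
      expect_true(all(diff(ep$start_min) > ep$duration_min[-nrow(ep)]))
  }
})

test_that("planted scaling factor is recovered from campaign output", {
  camp <- one_campaign()
  hv <- campaign_hourly_device(camp)
  dev_hourly <- counts_to_concentration(hv$hourly, 2.8, 60)
  S <- compute_scaling_factor(camp$reference$concentration_m3, dev_hourly)
  expect_lt(abs(S - 4.53) / 4.53, 0.1)
})
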