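test_that("class templates are deterministic, distinct and validated", {
  t1 <- generate_class_templates(c("starch", "other"), tiny_dims(), seed = 4)
  t2 <- generate_class_templates(c("starch", "other"), tiny_dims(), seed = 4)
  expect_identical(t1, t2)

  # two classes, separation floor 0: distinct random draws
  t0 <- generate_class_templates(c("starch", "other"), tiny_dims(), seed = 9,
                                 separation_floor = 0)
  v1 <- unlist(t0$templates$starch$signals)
  v2 <- unlist(t0$templates$other$signals)
  expect_gt(sqrt(sum((v1 - v2)^2)), 0)

  # 26 classes: 24 pollen-like + starch + other
  cls <- c(paste0("pollen_", 1:24), "starch", "other")
  t26 <- generate_class_templates(cls, tiny_dims(), seed = 2)
  expect_length(t26$templates, 26)

  expect_error(generate_class_templates(c("starch", "starch"), tiny_dims()),
               "duplicate")
  expect_error(generate_class_templates("starch", tiny_dims()), "2 classes")
})

test_that("labelled event generation honours counts, noise and seed", {
  cfg <- tiny_config()
  tpl <- tiny_templates()

  # exact per-class counts, including a 982-event total
  n982 <- c(starch = 246, broussonetia_like = 246, ulmus_like = 245,
            other = 245)
  b <- generate_particle_events(cfg, tpl, n_per_class = n982)
  expect_length(b, 982)
  expect_equal(sum(b$labels == "starch"), 246)

  b100 <- generate_particle_events(cfg, tpl, n_per_class = c(
    starch = 100, broussonetia_like = 2, ulmus_like = 2, other = 2))
  expect_equal(sum(b100$labels == "starch"), 100)

  expect_error(generate_particle_events(cfg, tpl, n_per_class = c(
    starch = 0, broussonetia_like = 1, ulmus_like = 1, other = 1)),
    "zero events")

  # zero noise: every starch event equals the starch template exactly
  cfg0 <- tiny_config(noise_sd = 0)
  b0 <- generate_particle_events(cfg0, tpl, n_per_class = 2)
  i <- which(b0$labels == "starch")[1]
  expect_equal(b0$signals$spectrum[i, , ],
               tpl$templates$starch$signals$spectrum)

  # reproducible from the master seed
  expect_identical(generate_particle_events(cfg, tpl, n_per_class = 5),
                   generate_particle_events(cfg, tpl, n_per_class = 5))
})

test_that("campaigns are deterministic and internally consistent", {
  cfg <- tiny_config()
  tpl <- tiny_templates()
  c1 <- generate_campaign(cfg, tpl)
  c2 <- generate_campaign(cfg, tpl)
  expect_identical(c1, c2)

  # hourly truth is the sum of per-minute truth over the hour
  hours <- (seq_along(c1$truth$minute_counts) - 1L) %/% 60L
  vol_h <- laser_spectrometer()$flow_rate_L_min * 60 / 1000
  expect_equal(c1$truth$hourly_concentration_m3,
               as.vector(rowsum(c1$truth$minute_counts, hours)) / vol_h)

  # event labels are conserved between batch and truth
  expect_identical(c1$events$labels[order(c1$events$timestamps)],
                   c1$truth$event_labels[order(c1$events$timestamps)])

  # default schedule: all episodes shorter than an hour, inside duration
  sch <- cfg$episode_schedule
  expect_true(all(sch$length_min < 60))
  expect_true(all(sch$start_min + sch$length_min <= cfg$duration_hours * 60))
})

test_that("empty emission schedule yields a starch-free device record", {
  cfg <- tiny_config(episode_schedule = data.frame(
    start_min = numeric(0), length_min = numeric(0), rate_per_min = numeric(0)))
  camp <- generate_campaign(cfg, tiny_templates(), signals = FALSE)
  expect_equal(sum(camp$events$labels == "starch"), 0)
  expect_equal(sum(camp$truth$minute_counts), 0)
})

test_that("device counts are an unbiased thinning of the truth", {
  # >= 100 replicates of a short campaign: empirical mean detection within
  # 3 standard errors of truth x efficiency
  tpl <- tiny_templates()
  sched <- data.frame(start_min = 10, length_min = 30, rate_per_min = 20)
  tot_dev <- 0; tot_truth <- 0
  dev_counts <- numeric(120)
  for (s in seq_len(120)) {
    cfg <- tiny_config(duration_hours = 1, episode_schedule = sched,
                       master_seed = 5000 + s)
    camp <- generate_campaign(cfg, tpl, signals = FALSE)
    dev_counts[s] <- sum(camp$truth$device_minute_counts)
    tot_truth <- tot_truth + sum(camp$truth$minute_counts)
  }
  eff <- 1 / tiny_config()$true_scaling_factor
  expected <- tot_truth * eff / 120
  se <- sd(dev_counts) / sqrt(120)
  expect_lt(abs(mean(dev_counts) - expected), 3 * se + 1e-9)
})

test_that("scenario configuration validates and round-trips through YAML", {
  expect_error(scenario_config(duration_hours = 0), "duration")
  expect_error(scenario_config(classes = c("starch", "a")), "'other'")
  expect_error(scenario_config(source_bearing_deg = 360), "360")
  expect_error(scenario_config(true_scaling_factor = -1), "> 0")
  expect_error(tiny_config(episode_schedule = data.frame(
    start_min = 230, length_min = 20, rate_per_min = 5)), "within")

  cfg <- tiny_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(back$classes, cfg$classes)
  expect_equal(back$true_scaling_factor, cfg$true_scaling_factor)
  expect_equal(back$episode_schedule$start_min, cfg$episode_schedule$start_min)
})
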