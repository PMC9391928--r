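# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small signal dimensions keep CNN tests fast while preserving the
# three-modality structure
tiny_dims <- function() {
  list(scattering = c(12L, 16L), spectrum = c(16L, 6L), lifetime = c(4L, 24L))
}

tiny_templates <- function() {
  cached("tiny_templates", function()
    generate_class_templates(c("starch", "broussonetia_like", "ulmus_like",
                               "other"),
                             signal_dims = tiny_dims(), seed = 11L))
}

tiny_config <- function(duration_hours = 4, master_seed = 3L, ...) {
  scenario_config(duration_hours = duration_hours,
                  signal_dims = tiny_dims(), master_seed = master_seed, ...)
}

# a quick labelled batch: 4 classes x 30 events at default noise
tiny_batch <- function() {
  cached("tiny_batch", function()
    generate_particle_events(tiny_config(), tiny_templates(), n_per_class = 30))
}

# one trained tiny model reused by several classifier tests
tiny_trained <- function() {
  cached("tiny_trained", function() {
    cfg <- classifier_config(tiny_config()$classes, epochs = 8L, seed = 5L)
    train_classifier(build_model(cfg, tiny_dims()), tiny_batch())
  })
}

# one full-scale campaign (240 h, default study conditions, no signal
# matrices) for single-campaign recovery checks
one_campaign <- function() {
  cached("one_campaign", function() {
    tpl <- generate_class_templates(scenario_config()$classes)
    generate_campaign(scenario_config(master_seed = 1001L), tpl,
                      signals = FALSE)
  })
}

# recovery statistics over 20 default campaigns, computed one campaign at
# a time (a 10 Hz wind table is ~200 MB; never hold 20 of them)
default_recoveries <- function(n_seeds = 20L) {
  cached("default_recoveries", function() {
    tpl <- generate_class_templates(scenario_config()$classes)
    S <- numeric(n_seeds); bearing_err <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      camp <- generate_campaign(scenario_config(master_seed = 1000L + s),
                                tpl, signals = FALSE)
      hv <- campaign_hourly_device(camp)
      dev_hourly <- counts_to_concentration(hv$hourly, 2.8, 60)
      S[s] <- compute_scaling_factor(camp$reference$concentration_m3,
                                     dev_hourly)
      hw <- hourly_vector_average(camp$wind)
      rose <- build_wind_rose(hw, select_high_starch_hours(hv$hourly, 2))
      b <- estimate_source_bearing(rose)
      bearing_err[s] <- angular_difference(b$circular_mean_deg,
                                           camp$truth$source_bearing_deg)
      rm(camp, hw); gc(FALSE)
    }
    list(scaling = S, bearing_error = bearing_err)
  })
}

# device starch counts per hour from a campaign's ground-truth labels
campaign_hourly_device <- function(camp) {
  n_min <- camp$config$duration_hours * 60
  dev_min <- minute_counts(camp$events$timestamps, camp$events$labels, n_min)
  list(minute = dev_min,
       hourly = as.vector(rowsum(dev_min, (seq_len(n_min) - 1L) %/% 60L)))
}
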