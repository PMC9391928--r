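#' Scenario configuration for a synthetic monitoring campaign
#'
#' Bundles every knob of the synthetic-campaign generator. The defaults are
#' the package's reference study conditions: a 240-hour campaign with four
#' particle classes (starch, two pollen-like confusers, "other"), one
#' 30-minute starch emission episode every four hours at 20 granules per
#' minute (episodes deliberately shorter than an hour), a planted source
#' bearing due north, a device detection efficiency of
#' `1/true_scaling_factor` so the linear calibration estimator is unbiased,
#' and a 10 Hz anemometer record whose hourly direction during episodes is
#' the source bearing plus centred noise.
#'
#' @param duration_hours campaign length in hours (>= 1).
#' @param classes class names; must include `"starch"` and `"other"`.
#' @param class_template_seed seed for [generate_class_templates()].
#' @param n_events_per_class_train labelled events per class for the
#'   training set; scalar or named vector over `classes`.
#' @param episode_schedule data.frame with columns `start_min`,
#'   `length_min`, `rate_per_min` (true starch granules per minute toward
#'   the sampler); `NULL` for the default 4-hourly schedule.
#' @param source_bearing_deg bearing the starch source lies at, degrees in
#'   [0, 360), 0 = north.
#' @param wind_noise_deg sd (degrees) of the hourly episodic wind direction
#'   around the source bearing.
#' @param true_scaling_factor planted device-to-reference scaling factor
#'   (> 0); the device detects each true granule with probability
#'   `1/true_scaling_factor`.
#' @param reference_efficiency_noise coefficient of variation of the
#'   multiplicative noise on reference hourly concentrations.
#' @param noise_sd sd of the additive Gaussian noise on signal matrices.
#' @param background_rate_per_min mean number of detected background
#'   particles per minute for each non-starch class.
#' @param signal_dims named list of `c(height, width)` per modality.
#' @param wind_hz anemometer sampling rate (Hz).
#' @param wind_speed_ms typical horizontal wind speed (m/s).
#' @param master_seed master seed; every stochastic stage derives from it.
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(duration_hours = 240,
                            classes = c("starch", "broussonetia_like",
                                        "ulmus_like", "other"),
                            class_template_seed = 101L,
                            n_events_per_class_train = 250L,
                            episode_schedule = NULL,
                            source_bearing_deg = 0,
                            wind_noise_deg = 15,
                            true_scaling_factor = 4.53,
                            reference_efficiency_noise = 0.1,
                            noise_sd = 0.25,
                            background_rate_per_min = 0.1,
                            signal_dims = default_signal_dims(),
                            wind_hz = 10,
                            wind_speed_ms = 3,
                            master_seed = 1L) {
  if (!is_number(duration_hours) || duration_hours < 1)
    stopf("duration_hours must be >= 1")
  classes <- as.character(classes)
  if (!all(c("starch", "other") %in% classes))
    stopf("classes must include 'starch' and 'other'")
  if (anyDuplicated(classes)) stopf("duplicate class names")
  if (is.null(episode_schedule))
    episode_schedule <- default_episode_schedule(duration_hours)
  episode_schedule <- as.data.frame(episode_schedule)
  need <- c("start_min", "length_min", "rate_per_min")
  if (!all(need %in% names(episode_schedule)))
    stopf("episode_schedule needs columns %s", paste(need, collapse = ", "))
  n_min <- duration_hours * 60
  if (nrow(episode_schedule)) {
    if (any(episode_schedule$length_min < 1))
      stopf("episode lengths must be >= 1 minute")
    if (any(episode_schedule$start_min < 0 |
              episode_schedule$start_min + episode_schedule$length_min > n_min))
      stopf("episode windows must lie within the campaign duration")
    if (any(episode_schedule$rate_per_min < 0))
      stopf("episode rates must be >= 0")
  }
  if (!is_number(source_bearing_deg) || source_bearing_deg < 0 ||
        source_bearing_deg >= 360)
    stopf("source_bearing_deg must lie in [0, 360)")
  if (!is_number(true_scaling_factor) || true_scaling_factor <= 0)
    stopf("true_scaling_factor must be > 0")
  if (true_scaling_factor < 1)
    stopf("true_scaling_factor < 1 implies detection efficiency > 1")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_number(wind_noise_deg) || wind_noise_deg < 0)
    stopf("wind_noise_deg must be >= 0")
  if (!is_number(reference_efficiency_noise) || reference_efficiency_noise < 0)
    stopf("reference_efficiency_noise must be >= 0")
  if (!is_count(master_seed)) stopf("master_seed must be a non-negative integer")
  structure(list(duration_hours = duration_hours, classes = classes,
                 class_template_seed = as.integer(class_template_seed),
                 n_events_per_class_train = n_events_per_class_train,
                 episode_schedule = episode_schedule,
                 source_bearing_deg = source_bearing_deg,
                 wind_noise_deg = wind_noise_deg,
                 true_scaling_factor = true_scaling_factor,
                 reference_efficiency_noise = reference_efficiency_noise,
                 noise_sd = noise_sd,
                 background_rate_per_min = background_rate_per_min,
                 signal_dims = signal_dims,
                 wind_hz = wind_hz, wind_speed_ms = wind_speed_ms,
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Default starch emission schedule
#'
#' One 30-minute episode every four hours, starting at minute 30 of the
#' hour, at a mean true emission of 20 granules per minute toward the
#' sampler. Episode lengths are below one hour by construction, matching
#' the sub-hour episode structure the campaign emulates.
#'
#' @param duration_hours campaign length in hours.
#' @return data.frame with `start_min`, `length_min`, `rate_per_min`.
#' @export
default_episode_schedule <- function(duration_hours) {
  starts <- seq(30, duration_hours * 60 - 30, by = 240)
  data.frame(start_min = starts, length_min = 30, rate_per_min = 20)
}

#' Read / write a scenario configuration as flat YAML
#' @param path YAML file path.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$episode_schedule))
    raw$episode_schedule <- do.call(rbind, lapply(raw$episode_schedule,
                                                  as.data.frame))
  if (!is.null(raw$signal_dims))
    raw$signal_dims <- lapply(raw$signal_dims, as.integer)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param config a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  out <- unclass(config)
  out$episode_schedule <- lapply(seq_len(nrow(config$episode_schedule)),
                                 function(i) as.list(config$episode_schedule[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

# draw one event batch from class templates: template + additive Gaussian
# noise per signal, lognormal diameters, given timestamps
draw_events <- function(templates, labels, timestamps, noise_sd) {
  n <- length(labels)
  dims <- templates$signal_dims
  signals <- lapply(dims, function(d) array(0, c(n, d[1L], d[2L])))
  diameters <- numeric(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    tpl <- templates$templates[[cl]]
    if (is.null(tpl)) stopf("no template for class '%s'", cl)
    diameters[idx] <- stats::rlnorm(length(idx), tpl$diameter$meanlog,
                                    tpl$diameter$sdlog)
    for (nm in names(dims)) {
      d <- dims[[nm]]
      base <- array(rep(tpl$signals[[nm]], each = length(idx)),
                    c(length(idx), d[1L], d[2L]))
      if (noise_sd > 0)
        base <- base + array(stats::rnorm(length(base), 0, noise_sd), dim(base))
      signals[[nm]][idx, , ] <- base
    }
  }
  event_batch(timestamps, diameters, signals, labels)
}

#' Generate a labelled training set of particle events
#'
#' Draws the requested number of events per class from the class templates:
#' diameters from the class lognormal, each signal matrix as the class mean
#' plus additive Gaussian noise. Reproducible from the configuration's
#' master seed.
#'
#' @param config a `scenario_config`.
#' @param templates a `class_templates` object covering `config$classes`.
#' @param n_per_class events per class; scalar or named vector. Defaults to
#'   `config$n_events_per_class_train`.
#' @return a labelled `event_batch` (timestamps are event indices in
#'   seconds).
#' @export
generate_particle_events <- function(config, templates,
                                     n_per_class = config$n_events_per_class_train) {
  if (!inherits(config, "scenario_config")) stopf("config must be a scenario_config")
  if (!inherits(templates, "class_templates"))
    stopf("templates must come from generate_class_templates()")
  classes <- config$classes
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)), classes)
  if (!all(classes %in% names(n_per_class)))
    stopf("n_per_class must name every class")
  n_per_class <- n_per_class[classes]
  if (any(n_per_class <= 0))
    stopf("zero events requested for class '%s'",
          classes[which(n_per_class <= 0)[1L]])
  labels <- rep(classes, times = n_per_class)
  with_seed(derive_seed(config$master_seed, 7L),
            draw_events(templates, labels, seq_along(labels), config$noise_sd))
}

# per-minute true starch counts implied by the episode schedule
true_minute_counts <- function(config) {
  n_min <- config$duration_hours * 60
  truth <- integer(n_min)
  sch <- config$episode_schedule
  for (i in seq_len(nrow(sch))) {
    idx <- sch$start_min[i] + seq_len(sch$length_min[i])  # 1-based minutes
    truth[idx] <- truth[idx] + stats::rpois(length(idx), sch$rate_per_min[i])
  }
  truth
}

# 10 Hz wind record: per-minute target direction (episodic hours point at
# the source bearing, others are uniform), small within-minute jitter
generate_wind <- function(config, episode_minute) {
  n_min <- config$duration_hours * 60
  hour_of_min <- (seq_len(n_min) - 1L) %/% 60L
  dir_min <- stats::runif(n_min, 0, 360)
  ep_hours <- unique(hour_of_min[episode_minute])
  if (length(ep_hours)) {
    hour_dir <- (config$source_bearing_deg +
                   stats::rnorm(length(ep_hours), 0, config$wind_noise_deg)) %% 360
    dir_min[episode_minute] <- hour_dir[match(hour_of_min[episode_minute],
                                              ep_hours)]
  }
  per_min <- as.integer(round(60 * config$wind_hz))
  n_s <- n_min * per_min
  dir_s <- rep(dir_min, each = per_min) + stats::rnorm(n_s, 0, 2)
  spd_base <- rep(ifelse(episode_minute, config$wind_speed_ms,
                         config$wind_speed_ms * 0.7), each = per_min)
  spd <- spd_base * exp(stats::rnorm(n_s, 0, 0.15))
  rad <- dir_s * pi / 180
  data.frame(time_s = (seq_len(n_s) - 1) / config$wind_hz,
             u_ms = -spd * sin(rad),
             v_ms = -spd * cos(rad))
}

#' Generate a complete synthetic campaign
#'
#' Produces the four co-located records the analysis consumes, all from one
#' master seed:
#' \itemize{
#'   \item a minute-stamped labelled `event_batch` of device-detected
#'     particles: starch detections are a binomial thinning of the true
#'     per-minute emission with detection efficiency
#'     `1/true_scaling_factor`, plus Poisson background events of every
#'     non-starch class;
#'   \item an hourly reference-sampler table (`hour_index`,
#'     `concentration_m3`): the true hourly concentration times unbiased
#'     multiplicative noise, so the linear calibration estimator recovers
#'     the planted scaling factor in expectation;
#'   \item a 10 Hz wind table (`time_s`, `u_ms`, `v_ms`) whose hourly
#'     direction during episode hours is the source bearing plus centred
#'     noise and uniform otherwise;
#'   \item the ground truth (per-minute true counts, per-hour true
#'     concentration, planted bearing, event labels).
#' }
#'
#' @param config a `scenario_config`.
#' @param templates matching `class_templates`.
#' @param signals if `FALSE`, skip synthesizing per-event signal matrices
#'   (labels, timestamps and diameters are always generated); useful for
#'   calibration and wind studies that never classify.
#' @return a `campaign` list: `events`, `reference`, `wind`, `truth`.
#' @export
generate_campaign <- function(config, templates, signals = TRUE) {
  if (!inherits(config, "scenario_config")) stopf("config must be a scenario_config")
  with_seed(derive_seed(config$master_seed, 13L), {
    n_min <- config$duration_hours * 60
    n_h <- config$duration_hours
    truth_min <- true_minute_counts(config)
    eff <- 1 / config$true_scaling_factor
    device_min <- stats::rbinom(n_min, truth_min, eff)

    # device flow defines the count<->concentration volume
    flow <- laser_spectrometer()$flow_rate_L_min
    vol_h_m3 <- flow * 60 / 1000
    hour_of_min <- (seq_len(n_min) - 1L) %/% 60L
    truth_h <- as.vector(rowsum(truth_min, hour_of_min))
    true_conc_h <- truth_h / vol_h_m3

    cv <- config$reference_efficiency_noise
    noise_h <- if (cv > 0)
      stats::rgamma(n_h, shape = 1 / cv^2, rate = 1 / cv^2) else rep(1, n_h)
    reference <- data.frame(hour_index = seq_len(n_h) - 1L,
                            concentration_m3 = true_conc_h * noise_h)

    # device-detected events: starch detections + class-wise background
    ev_min <- rep.int(seq_len(n_min) - 1L, device_min)
    ev_lab <- rep("starch", length(ev_min))
    for (cl in setdiff(config$classes, "starch")) {
      bg <- stats::rpois(n_min, config$background_rate_per_min)
      ev_min <- c(ev_min, rep.int(seq_len(n_min) - 1L, bg))
      ev_lab <- c(ev_lab, rep(cl, sum(bg)))
    }
    ts <- ev_min * 60 + stats::runif(length(ev_min), 0, 60)
    ord <- order(ts)
    ts <- ts[ord]; ev_lab <- ev_lab[ord]
    events <- if (signals) {
      draw_events(templates, ev_lab, ts, config$noise_sd)
    } else {
      diam <- numeric(length(ev_lab))
      for (cl in unique(ev_lab)) {
        idx <- which(ev_lab == cl)
        dd <- templates$templates[[cl]]$diameter
        diam[idx] <- stats::rlnorm(length(idx), dd$meanlog, dd$sdlog)
      }
      event_batch(ts, diam, list(), ev_lab)
    }

    episode_minute <- truth_min > 0
    wind <- generate_wind(config, episode_minute)

    truth <- list(minute_counts = truth_min,
                  device_minute_counts = device_min,
                  hourly_concentration_m3 = true_conc_h,
                  source_bearing_deg = config$source_bearing_deg,
                  event_labels = ev_lab)
    structure(list(events = events, reference = reference, wind = wind,
                   truth = truth, config = config),
              class = "campaign")
  })
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(paste0("<campaign: %d h, %d device events, %d episode minutes, ",
                     "planted S = %.3g, bearing = %.1f deg>\n"),
              x$config$duration_hours, length(x$events),
              sum(x$truth$minute_counts > 0), x$config$true_scaling_factor,
              x$truth$source_bearing_deg))
  invisible(x)
}
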