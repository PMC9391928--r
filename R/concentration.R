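# Counts -> concentrations, linear cross-calibration against the reference
# sampler, episode detection, and mass concentration.

#' Time-binned number-concentration series
#'
#' @param bin_start_min start minute of each bin (contiguous,
#'   non-overlapping).
#' @param values number concentrations in granules per cubic metre
#'   (>= 0).
#' @param bin_width_min bin width in minutes (1 for device-resolution
#'   series, 60 for hourly).
#' @return a `concentration_series`.
#' @export
concentration_series <- function(bin_start_min, values, bin_width_min = 1) {
  if (length(bin_start_min) != length(values))
    stopf("bin starts and values differ in length")
  if (length(values) && any(!is.finite(values))) stopf("values must be finite")
  if (length(values) && any(values < 0)) stopf("concentrations must be >= 0")
  if (length(bin_start_min) > 1 &&
        any(abs(diff(bin_start_min) - bin_width_min) > 1e-9))
    stopf("bins must be contiguous and non-overlapping")
  structure(list(bin_start_min = as.numeric(bin_start_min),
                 bin_width_min = bin_width_min,
                 values = as.numeric(values)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series: %d bins of %g min, max %s granules/m3>\n",
              length(x$values), x$bin_width_min,
              if (length(x$values)) format(round(max(x$values))) else "NA"))
  invisible(x)
}

#' @export
as.data.frame.concentration_series <- function(x, ...) {
  data.frame(bin_start_min = x$bin_start_min, value = x$values)
}

#' Convert particle counts to number concentration
#'
#' `count / (flow_L_min * window_min / 1000)` granules per cubic metre.
#' At the laser spectrometer's 2.8 L/min, 20 counts in one minute is
#' 7142.86 granules/m3 (printed as 7143).
#'
#' @param count particle count(s), >= 0 (vectorized).
#' @param flow_L_min sampler flow in litres per minute, > 0.
#' @param window_min counting window in minutes, > 0.
#' @return concentration(s) in granules per cubic metre.
#' @export
counts_to_concentration <- function(count, flow_L_min, window_min = 1) {
  if (!is_number(flow_L_min) || flow_L_min <= 0)
    stopf("flow_L_min must be a single positive number")
  if (!is_number(window_min) || window_min <= 0)
    stopf("window_min must be a single positive number")
  if (length(count) && any(count < 0)) stopf("counts must be >= 0")
  count / (flow_L_min * window_min / 1000)
}

#' Aggregate a minute series to hourly resolution
#'
#' With constant flow, the hourly concentration (total counts over total
#' sampled volume) equals the mean of the 60 minute concentrations. A
#' partial trailing hour is excluded with a message.
#'
#' @param series a 1-minute `concentration_series`.
#' @return an hourly `concentration_series`.
#' @export
aggregate_hourly <- function(series) {
  if (!inherits(series, "concentration_series"))
    stopf("series must be a concentration_series")
  if (series$bin_width_min != 1) stopf("expected a 1-minute series")
  n <- length(series$values)
  if (n == 0)
    return(concentration_series(numeric(0), numeric(0), bin_width_min = 60))
  n_full <- n %/% 60L
  if (n %% 60L != 0L)
    message(sprintf("aggregate_hourly: dropping partial trailing hour (%d min)",
                    n %% 60L))
  if (n_full == 0)
    return(concentration_series(numeric(0), numeric(0), bin_width_min = 60))
  keep <- seq_len(n_full * 60L)
  hourly <- colMeans(matrix(series$values[keep], nrow = 60L))
  concentration_series(series$bin_start_min[1] + (seq_len(n_full) - 1L) * 60,
                       hourly, bin_width_min = 60)
}

#' Linear scaling factor between reference and device series
#'
#' The calibration estimator: the sum of reference hourly concentrations
#' over the calibration bins divided by the sum of the device hourly
#' concentrations over the same bins.
#'
#' @param reference numeric vector (or hourly `concentration_series`) of
#'   reference concentrations.
#' @param device aligned device concentrations.
#' @param calibration_bins indices of the bins used for calibration
#'   (default: all).
#' @return the scaling factor S (> 0).
#' @export
compute_scaling_factor <- function(reference, device,
                                   calibration_bins = seq_along(ref_values(reference))) {
  ref <- ref_values(reference); dev <- ref_values(device)
  if (length(ref) != length(dev))
    stopf("reference (%d) and device (%d) series differ in length",
          length(ref), length(dev))
  if (length(calibration_bins) &&
        (min(calibration_bins) < 1 || max(calibration_bins) > length(ref)))
    stopf("calibration_bins out of range")
  sr <- sum(ref[calibration_bins]); sd_ <- sum(dev[calibration_bins])
  if (sd_ <= 0) stopf("undefined scaling factor: device sum over calibration bins is 0")
  sr / sd_
}

ref_values <- function(x) {
  if (inherits(x, "concentration_series")) x$values else as.numeric(x)
}

#' Apply a linear scaling factor to a series
#' @param series a `concentration_series` or numeric vector.
#' @param S scaling factor, > 0.
#' @export
apply_scaling <- function(series, S) {
  if (!is_number(S) || S <= 0) stopf("S must be a single positive number")
  if (inherits(series, "concentration_series")) {
    series$values <- series$values * S
    series
  } else series * S
}

#' Pearson product-moment correlation
#'
#' Validated wrapper used for device-vs-reference agreement: requires equal
#' length >= 3 and nonzero variance in both inputs. The two-sided t-based
#' p-value is attached as attribute `"p.value"` (reported descriptively,
#' never used as a gate).
#'
#' @param x,y numeric vectors.
#' @return the correlation coefficient r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  attr(r, "p.value") <- ct$p.value
  r
}

#' Calibrate a device series against the reference sampler
#'
#' Computes the scaling factor on the calibration bins and validates by
#' Pearson correlation between the scaled device series and the reference
#' on the validation bins, which are enforced to be disjoint from the
#' calibration bins.
#'
#' @param reference,device aligned hourly series (vectors or
#'   `concentration_series`).
#' @param calibration_bins bin indices used to fit S.
#' @param validation_bins bin indices used for the correlation check;
#'   default: all bins not used for calibration.
#' @return a `calibration_result`: `scaling_factor`, `pearson_r`,
#'   `p_value`, `n_calibration`, `n_validation`.
#' @export
calibrate_concentrations <- function(reference, device, calibration_bins,
                                     validation_bins = NULL) {
  ref <- ref_values(reference); dev <- ref_values(device)
  if (is.null(validation_bins))
    validation_bins <- setdiff(seq_along(ref), calibration_bins)
  if (length(intersect(calibration_bins, validation_bins)))
    stopf("validation bins must be disjoint from calibration bins")
  S <- compute_scaling_factor(ref, dev, calibration_bins)
  r <- pearson_r(dev[validation_bins] * S, ref[validation_bins])
  structure(list(scaling_factor = S, pearson_r = as.numeric(r),
                 p_value = attr(r, "p.value"),
                 n_calibration = length(calibration_bins),
                 n_validation = length(validation_bins)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration: S = %.3f over %d bins; validation r = %.3f (p = %.2g, n = %d)>\n",
              x$scaling_factor, x$n_calibration, x$pearson_r, x$p_value,
              x$n_validation))
  invisible(x)
}

#' Mass-concentration model for spherical granules
#'
#' Starch granules are modelled as spheres of density `density_g_cm3`
#' (default 1.5) and diameter `diameter_um` (default 10), so a number
#' concentration N per cubic metre corresponds to
#' `N * (pi/6) d^3 rho` of airborne mass: 10,000 granules/m3 is about
#' 0.008 mg/m3.
#'
#' @param density_g_cm3 granule density, > 0.
#' @param diameter_um granule diameter, > 0.
#' @return a `mass_model` list.
#' @export
mass_model <- function(density_g_cm3 = 1.5, diameter_um = 10) {
  if (!is_number(density_g_cm3) || density_g_cm3 <= 0)
    stopf("density must be > 0")
  if (!is_number(diameter_um) || diameter_um <= 0)
    stopf("diameter must be > 0")
  structure(list(density_g_cm3 = density_g_cm3, diameter_um = diameter_um,
                 spherical = TRUE),
            class = "mass_model")
}

#' Mass concentration from number concentration
#'
#' @param number_conc_m3 number concentration(s) in granules per cubic
#'   metre, >= 0 (vectorized).
#' @param model a [mass_model()].
#' @return mass concentration(s) in mg per cubic metre.
#' @export
mass_concentration <- function(number_conc_m3, model = mass_model()) {
  if (!inherits(model, "mass_model")) stopf("model must come from mass_model()")
  if (length(number_conc_m3) && any(number_conc_m3 < 0))
    stopf("number concentrations must be >= 0")
  d_m <- model$diameter_um * 1e-6
  rho_kg_m3 <- model$density_g_cm3 * 1000
  mass_kg <- (pi / 6) * d_m^3 * rho_kg_m3     # kg per granule
  number_conc_m3 * mass_kg * 1e6              # mg per m3
}

#' Detect concentration episodes in a minute series
#'
#' An episode is a maximal run of consecutive minutes with concentration
#' strictly above the threshold; in the monitored setting such episodes are
#' typically shorter than an hour (sudden increase, sudden decrease).
#'
#' @param series a 1-minute `concentration_series` (or numeric vector).
#' @param threshold concentration threshold, >= 0.
#' @return data.frame with `start_min`, `duration_min`, `peak`.
#' @export
detect_episodes <- function(series, threshold = 0) {
  if (!is_number(threshold) || threshold < 0) stopf("threshold must be >= 0")
  v <- ref_values(series)
  start0 <- if (inherits(series, "concentration_series"))
    series$bin_start_min[1] else 0
  if (!length(v))
    return(data.frame(start_min = numeric(0), duration_min = numeric(0),
                      peak = numeric(0)))
  above <- v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_min = start0 + starts[keep] - 1L,
             duration_min = r$lengths[keep],
             peak = vapply(keep, function(i) max(v[starts[i]:ends[i]]), 1))
}

#' Per-minute starch counts from classified events
#'
#' Tabulates, for each minute of the campaign, the number of events whose
#' (predicted or true) label equals `class`.
#'
#' @param timestamps event timestamps in seconds from campaign start.
#' @param labels event labels, aligned with `timestamps`.
#' @param n_minutes total number of minutes in the campaign.
#' @param class label to count (default `"starch"`).
#' @return integer vector of length `n_minutes`.
#' @export
minute_counts <- function(timestamps, labels, n_minutes, class = "starch") {
  sel <- labels == class
  mins <- floor(timestamps[sel] / 60)
  counts <- integer(n_minutes)
  if (any(sel)) {
    tab <- table(factor(mins, levels = 0:(n_minutes - 1L)))
    counts <- as.integer(tab)
  }
  counts
}

#' Read / write a concentration series CSV
#' @param series a `concentration_series`.
#' @param file CSV path (columns `bin_start_min`, `value`).
#' @export
write_series_csv <- function(series, file) {
  data.table::fwrite(as.data.frame(series), file)
  invisible(file)
}

#' @rdname write_series_csv
#' @param bin_width_min bin width of the stored series.
#' @export
read_series_csv <- function(file, bin_width_min = 1) {
  d <- data.table::fread(file)
  concentration_series(d$bin_start_min, d$value, bin_width_min)
}
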