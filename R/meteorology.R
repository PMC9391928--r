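# Wind handling: u/v components -> meteorological direction, hourly vector
# averaging, high-starch hour selection, 16-sector wind roses and source
# bearing estimation.
#
# Coordinate convention (important -- sign errors flip the rose): u is the
# eastward wind component, v the northward component, both in m/s. The
# meteorological direction is the compass bearing the wind blows FROM,
# 0 deg = north, 90 deg = east.

SECTOR_NAMES <- c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
                  "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")

#' Convert wind components to meteorological direction
#'
#' `direction = (270 - atan2(v, u) * 180/pi) mod 360`: air moving southward
#' (`u = 0, v = -1`) comes from the north (0 deg); `u = -1, v = 0` is an
#' easterly (90 deg).
#'
#' @param u eastward component(s), m/s.
#' @param v northward component(s), m/s (same length).
#' @return directions in degrees in [0, 360); `NA` for calm (0, 0) pairs.
#' @export
uv_to_direction <- function(u, v) {
  if (length(u) != length(v)) stopf("u and v differ in length")
  d <- wrap360((270 - atan2(v, u) * 180 / pi))
  d[u == 0 & v == 0] <- NA_real_
  d
}

# degrees into [0, 360); folds float residue at the 360 boundary onto 0
wrap360 <- function(d) {
  d <- d %% 360
  d[d > 360 - 1e-9] <- 0
  d
}

#' Unit wind vector for a meteorological direction
#'
#' Inverse of [uv_to_direction()] at unit speed: the air moves towards the
#' opposite compass point, so `u = -sin(theta)`, `v = -cos(theta)`.
#'
#' @param direction_deg direction(s) in degrees.
#' @param speed wind speed(s), m/s.
#' @return data.frame with `u` and `v`.
#' @export
direction_to_uv <- function(direction_deg, speed = 1) {
  rad <- direction_deg * pi / 180
  data.frame(u = -speed * sin(rad), v = -speed * cos(rad))
}

#' Hourly vector-averaged wind
#'
#' Averages the raw u/v samples within each hour (speed-weighted vector
#' mean); the hourly direction is the direction of the mean vector and the
#' hourly speed its magnitude. Hours whose mean speed falls below
#' `calm_threshold` are flagged calm (`NA` direction) and are excluded from
#' wind roses.
#'
#' @param wind data.frame with columns `time_s`, `u_ms`, `v_ms` (any
#'   sampling rate; 10 Hz in the reference setup).
#' @param calm_threshold mean speed (m/s) below which an hour is calm.
#' @return data.frame of class `hourly_wind`: `hour`, `direction_deg`,
#'   `speed_ms`, `calm`.
#' @export
hourly_vector_average <- function(wind, calm_threshold = 0.1) {
  need <- c("time_s", "u_ms", "v_ms")
  if (!all(need %in% names(wind)))
    stopf("wind needs columns %s", paste(need, collapse = ", "))
  if (!nrow(wind))
    return(structure(data.frame(hour = integer(0), direction_deg = numeric(0),
                                speed_ms = numeric(0), calm = logical(0)),
                     class = c("hourly_wind", "data.frame")))
  hour <- as.integer(wind$time_s %/% 3600)
  cnt <- rowsum(rep.int(1L, length(hour)), hour)
  um <- rowsum(wind$u_ms, hour) / cnt
  vm <- rowsum(wind$v_ms, hour) / cnt
  hours <- as.integer(rownames(um))
  speed <- sqrt(um[, 1]^2 + vm[, 1]^2)
  dir <- uv_to_direction(um[, 1], vm[, 1])
  calm <- speed < calm_threshold
  dir[calm] <- NA_real_
  structure(data.frame(hour = hours, direction_deg = unname(dir),
                       speed_ms = unname(speed), calm = unname(calm)),
            class = c("hourly_wind", "data.frame"))
}

#' Select high-starch hours
#'
#' Hours whose raw device starch count is strictly greater than the
#' threshold (default: more than 2 starch particles per hour) are the
#' conditioning set for source-attribution wind roses.
#'
#' @param hourly_counts integer vector of device starch counts per hour
#'   (hour 0 first).
#' @param threshold count threshold; strictly-greater rule.
#' @return 0-based hour indices.
#' @export
select_high_starch_hours <- function(hourly_counts, threshold = 2) {
  which(hourly_counts > threshold) - 1L
}

#' Build a 16-sector wind rose
#'
#' Assigns each selected non-calm hour to one of 16 sectors of 22.5 deg
#' centred on the compass points (sector N spans [348.75, 11.25)).
#'
#' @param hourly a `hourly_wind` data.frame.
#' @param hours 0-based hour indices to include (default: all).
#' @return a `wind_rose`: per-sector `counts` and `fraction`, plus the
#'   contributing hourly directions.
#' @export
build_wind_rose <- function(hourly, hours = hourly$hour) {
  sel <- hourly[hourly$hour %in% hours & !hourly$calm &
                  !is.na(hourly$direction_deg), , drop = FALSE]
  sector <- sector_of(sel$direction_deg)
  counts <- as.integer(table(factor(sector, levels = SECTOR_NAMES)))
  names(counts) <- SECTOR_NAMES
  n <- sum(counts)
  structure(list(counts = counts,
                 fraction = if (n > 0) counts / n else counts * 0,
                 n_hours = n,
                 directions = sel$direction_deg),
            class = "wind_rose")
}

# sector of a direction: 22.5-deg sectors centred on N, NNE, ...
sector_of <- function(direction_deg) {
  idx <- floor(((direction_deg + 11.25) %% 360) / 22.5) + 1L
  SECTOR_NAMES[idx]
}

#' @export
print.wind_rose <- function(x, ...) {
  cat(sprintf("<wind_rose: %d hours>\n", x$n_hours))
  nz <- x$counts[x$counts > 0]
  if (length(nz))
    cat(" ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.wind_rose <- function(x, main = "Wind rose", ...) {
  theta <- (90 - seq(0, 337.5, by = 22.5)) * pi / 180
  r <- x$fraction
  lim <- max(r, 0.05) * 1.2
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_along(theta)) {
    a0 <- theta[i] - pi / 16; a1 <- theta[i] + pi / 16
    aa <- seq(a0, a1, length.out = 10)
    graphics::polygon(c(0, r[i] * cos(aa)), c(0, r[i] * sin(aa)),
                      col = "steelblue", border = "white")
  }
  lab_r <- lim * 0.95
  graphics::text(lab_r * cos(theta[c(1, 5, 9, 13)]),
                 lab_r * sin(theta[c(1, 5, 9, 13)]),
                 c("N", "E", "S", "W"))
  invisible(x)
}

#' Circular mean of directions
#' @param direction_deg directions in degrees.
#' @return mean direction in [0, 360).
#' @export
circular_mean <- function(direction_deg) {
  rad <- direction_deg * pi / 180
  wrap360(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

#' Estimate the source bearing from a wind rose
#'
#' The modal sector (ties: all reported) and the circular mean of the
#' contributing hourly directions. Since the meteorological direction is
#' where the wind comes FROM, the modal direction over high-starch hours
#' points at the emission source.
#'
#' @param rose a `wind_rose`.
#' @return list with `modal_sector` (character, >= 1 on ties) and
#'   `circular_mean_deg`.
#' @export
estimate_source_bearing <- function(rose) {
  if (!inherits(rose, "wind_rose")) stopf("rose must be a wind_rose")
  if (rose$n_hours == 0) stopf("empty wind rose")
  m <- max(rose$counts)
  list(modal_sector = names(rose$counts)[rose$counts == m],
       circular_mean_deg = circular_mean(rose$directions))
}

#' Smallest absolute angular difference between two bearings
#' @param a,b bearings in degrees.
#' @return difference in [0, 180].
#' @export
angular_difference <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Read / write wind and rose CSV files
#' @param wind data.frame with `time_s`, `u_ms`, `v_ms`.
#' @param file CSV path.
#' @export
write_wind_csv <- function(wind, file) {
  data.table::fwrite(wind[, c("time_s", "u_ms", "v_ms")], file)
  invisible(file)
}

#' @rdname write_wind_csv
#' @export
read_wind_csv <- function(file) {
  as.data.frame(data.table::fread(file, select = c("time_s", "u_ms", "v_ms")))
}

#' @rdname write_wind_csv
#' @param rose a `wind_rose`.
#' @export
write_rose_csv <- function(rose, file) {
  data.table::fwrite(data.frame(sector = names(rose$counts),
                                count = as.integer(rose$counts),
                                fraction = as.numeric(rose$fraction)), file)
  invisible(file)
}
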