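# Simplified Lagrangian Gaussian-puff dispersion.
#
# A desk-scale stand-in for a full puff model: discrete puffs released from
# a point source, advected by the wind, spreading linearly with travel
# distance, with per-size-bin gravitational settling (Stokes law) and
# deposition when a bin's centroid reaches the ground. Concentration fields
# come from 3-D Gaussian kernels with ground reflection, evaluated at
# receptor height. No terrain, buildings or stability classes.

#' Point emission source
#'
#' @param x,y source position, m.
#' @param height release height, m (default 1.5).
#' @param radius source radius, m (default 1); used as the initial
#'   horizontal puff spread.
#' @param emission_g_s continuous emission rate Q in g/s (default 1).
#' @param exit_velocity_ms vertical exit velocity, m/s (default 18; kept as
#'   metadata, no plume-rise model).
#' @return a `point_source`.
#' @export
point_source <- function(x = 0, y = 0, height = 1.5, radius = 1,
                         emission_g_s = 1, exit_velocity_ms = 18) {
  if (!is_number(emission_g_s) || emission_g_s < 0) stopf("Q must be >= 0")
  if (!is_number(height) || height < 0) stopf("height must be >= 0")
  if (!is_number(radius) || radius <= 0) stopf("radius must be > 0")
  structure(list(x = x, y = y, height = height, radius = radius,
                 emission_g_s = emission_g_s,
                 exit_velocity_ms = exit_velocity_ms),
            class = "point_source")
}

#' Lognormal particle-size distribution
#'
#' @param gmd_um geometric mass mean diameter, um (default 10).
#' @param gsd geometric standard deviation, dimensionless >= 1 (default 4).
#' @param n_bins number of equal-mass bins (default 5).
#' @return a `size_distribution`.
#' @export
size_distribution <- function(gmd_um = 10, gsd = 4, n_bins = 5L) {
  if (!is_number(gmd_um) || gmd_um <= 0) stopf("GMD must be > 0")
  if (!is_number(gsd) || gsd < 1) stopf("GSD must be >= 1")
  if (!is_count(n_bins) || n_bins < 1) stopf("n_bins must be >= 1")
  structure(list(gmd_um = gmd_um, gsd = gsd, n_bins = as.integer(n_bins)),
            class = "size_distribution")
}

#' Equal-mass size bins of a lognormal distribution
#'
#' Partitions the lognormal mass distribution at equal-probability
#' quantiles: each of the `n_bins` bins carries mass fraction `1/n_bins`
#' and is represented by the diameter at its probability midpoint, so the
#' middle bin of an odd split sits exactly at the GMD (the lognormal
#' median). A GSD of 1 collapses to a single bin at the GMD.
#'
#' @param dist a [size_distribution()].
#' @return data.frame with `diameter_um` and `mass_fraction` (summing to 1).
#' @export
size_bins <- function(dist) {
  if (!inherits(dist, "size_distribution"))
    stopf("dist must come from size_distribution()")
  n <- dist$n_bins
  if (dist$gsd == 1)
    return(data.frame(diameter_um = dist$gmd_um, mass_fraction = 1))
  p_mid <- (seq_len(n) - 0.5) / n
  data.frame(diameter_um = stats::qlnorm(p_mid, meanlog = log(dist$gmd_um),
                                         sdlog = log(dist$gsd)),
             mass_fraction = rep(1 / n, n))
}

#' Stokes gravitational settling velocity
#'
#' `v = rho * g * d^2 / (18 mu)` for a small sphere; valid in the Stokes
#' regime, guarded here at 100 um.
#'
#' @param diameter_um particle diameter(s), um, <= 100.
#' @param density_kg_m3 particle density (default 1500, starch).
#' @param viscosity_pa_s dynamic viscosity of air (default 1.81e-5).
#' @return settling velocity in m/s.
#' @export
settling_velocity <- function(diameter_um, density_kg_m3 = 1500,
                              viscosity_pa_s = 1.81e-5) {
  if (any(diameter_um < 0)) stopf("diameter must be >= 0")
  if (any(diameter_um > 100))
    stopf("diameter %.3g um exceeds the Stokes-regime guard (100 um)",
          max(diameter_um))
  d_m <- diameter_um * 1e-6
  density_kg_m3 * 9.81 * d_m^2 / (18 * viscosity_pa_s)
}

#' Receptor grid for concentration fields
#'
#' @param origin_x,origin_y south-west corner, m.
#' @param spacing grid spacing, m (default 50).
#' @param nx,ny number of grid points per axis (default 101, capped design
#'   limit 301).
#' @param receptor_height evaluation height, m.
#' @return a `dispersion_grid`.
#' @export
dispersion_grid <- function(origin_x = 0, origin_y = 0, spacing = 50,
                            nx = 101L, ny = 101L, receptor_height = 1.5) {
  if (!is_number(spacing) || spacing <= 0) stopf("spacing must be > 0")
  if (nx > 301L || ny > 301L) stopf("grid extent capped at 301 x 301")
  structure(list(origin_x = origin_x, origin_y = origin_y, spacing = spacing,
                 nx = as.integer(nx), ny = as.integer(ny),
                 receptor_height = receptor_height,
                 xs = origin_x + (seq_len(nx) - 1L) * spacing,
                 ys = origin_y + (seq_len(ny) - 1L) * spacing),
            class = "dispersion_grid")
}

# puff ensemble: parallel vectors/matrices over puffs; z and mass are
# per-puff x per-bin because bins settle at different speeds
new_puff_state <- function(bins, sigma_h0, sigma_z0) {
  structure(list(x = numeric(0), y = numeric(0),
                 z = matrix(numeric(0), 0, nrow(bins)),
                 mass = matrix(numeric(0), 0, nrow(bins)),
                 travel = numeric(0),
                 sigma_h0 = sigma_h0, sigma_z0 = sigma_z0,
                 bins = bins,
                 v_settle = settling_velocity(bins$diameter_um),
                 deposited = numeric(nrow(bins)),
                 emitted = 0),
            class = "puff_state")
}

release_puff <- function(puffs, source, mass_g) {
  nb <- nrow(puffs$bins)
  puffs$x <- c(puffs$x, source$x)
  puffs$y <- c(puffs$y, source$y)
  puffs$z <- rbind(puffs$z, rep(source$height, nb))
  puffs$mass <- rbind(puffs$mass, mass_g * puffs$bins$mass_fraction)
  puffs$travel <- c(puffs$travel, 0)
  puffs$emitted <- puffs$emitted + mass_g
  puffs
}

#' Advance a puff ensemble by one time step
#'
#' Centroids advect with the wind; each size bin additionally settles at
#' its Stokes velocity. Horizontal and vertical spreads grow linearly with
#' travel distance (`sigma = sigma0 + I * distance`). Bins whose centroid
#' reaches the ground deposit their mass into the deposition ledger, so
#' emitted mass always equals airborne plus deposited mass.
#'
#' @param puffs a `puff_state`.
#' @param u,v wind components at this step, m/s.
#' @param dt time step, s (> 0).
#' @param spread_h,spread_z linear spread coefficients (defaults 0.1 and
#'   0.05 per metre of travel).
#' @return the advanced `puff_state`.
#' @export
step_puffs <- function(puffs, u, v, dt, spread_h = 0.1, spread_z = 0.05) {
  if (!is_number(dt) || dt <= 0) stopf("dt must be > 0")
  if (!length(puffs$x)) return(puffs)
  puffs$x <- puffs$x + u * dt
  puffs$y <- puffs$y + v * dt
  puffs$z <- puffs$z - matrix(puffs$v_settle, nrow(puffs$z), ncol(puffs$z),
                              byrow = TRUE) * dt
  puffs$travel <- puffs$travel + sqrt(u^2 + v^2) * dt
  grounded <- puffs$z <= 0 & puffs$mass > 0
  if (any(grounded)) {
    puffs$deposited <- puffs$deposited + colSums(puffs$mass * grounded)
    puffs$mass[grounded] <- 0
    puffs$z[puffs$z < 0] <- 0
  }
  puffs
}

#' Ground-level concentration field of a puff ensemble
#'
#' Each puff contributes a 3-D Gaussian kernel (mass-normalized, with an
#' image source mirrored at the ground) evaluated at the grid's receptor
#' height:
#' `C = m / ((2 pi)^{3/2} sh^2 sz) * exp(-r^2/(2 sh^2)) *
#'  (exp(-(zr - zc)^2/(2 sz^2)) + exp(-(zr + zc)^2/(2 sz^2)))`.
#'
#' @param puffs a `puff_state` (after at least one step, so spreads are
#'   positive).
#' @param grid a [dispersion_grid()].
#' @param spread_h,spread_z linear spread coefficients, must match the ones
#'   used in [step_puffs()].
#' @return matrix `nx x ny` of concentrations in g/m3 (x varies along
#'   rows).
#' @export
concentration_field <- function(puffs, grid, spread_h = 0.1, spread_z = 0.05) {
  field <- matrix(0, grid$nx, grid$ny)
  if (!length(puffs$x)) return(field)
  sh <- puffs$sigma_h0 + spread_h * puffs$travel
  sz <- puffs$sigma_z0 + spread_z * puffs$travel
  zr <- grid$receptor_height
  for (i in seq_along(puffs$x)) {
    m_air <- sum(puffs$mass[i, ])
    if (m_air <= 0) next
    gx <- exp(-(grid$xs - puffs$x[i])^2 / (2 * sh[i]^2))
    gy <- exp(-(grid$ys - puffs$y[i])^2 / (2 * sh[i]^2))
    # per-bin vertical term (bins settle to different heights)
    for (b in seq_len(ncol(puffs$mass))) {
      mb <- puffs$mass[i, b]
      if (mb <= 0) next
      zc <- puffs$z[i, b]
      vert <- exp(-(zr - zc)^2 / (2 * sz[i]^2)) +
        exp(-(zr + zc)^2 / (2 * sz[i]^2))
      norm <- mb / ((2 * pi)^1.5 * sh[i]^2 * sz[i])
      field <- field + norm * vert * outer(gx, gy)
    }
  }
  field
}

#' Run a puff-dispersion simulation
#'
#' Releases one puff per `release_interval` carrying
#' `Q * release_interval` grams split across the size bins, advects the
#' ensemble through the wind series, and records ground-level concentration
#' fields at the requested output interval.
#'
#' @param source a [point_source()].
#' @param dist a [size_distribution()].
#' @param wind either a data.frame (`time_s`, `u_ms`, `v_ms`; interpolated
#'   as a step function) or a function `time -> c(u, v)`.
#' @param grid a [dispersion_grid()].
#' @param duration_s total simulated time, s.
#' @param release_interval_s seconds between puff releases (default 10).
#' @param dt time step, s (default 10).
#' @param output_every_s interval between stored fields (default 100).
#' @param spread_h,spread_z linear spread coefficients.
#' @return a `dispersion_run`: `fields` (named by time), `times`, final
#'   `puffs`, `deposited`, `emitted`, and mass-conservation error.
#' @export
run_dispersion <- function(source, dist, wind, grid,
                           duration_s = 600, release_interval_s = 10,
                           dt = 10, output_every_s = 100,
                           spread_h = 0.1, spread_z = 0.05) {
  wind_at <- if (is.function(wind)) wind else {
    function(t) {
      i <- findInterval(t, wind$time_s)
      i <- max(i, 1L)
      c(wind$u_ms[i], wind$v_ms[i])
    }
  }
  bins <- size_bins(dist)
  puffs <- new_puff_state(bins, sigma_h0 = source$radius,
                          sigma_z0 = source$radius / 2)
  fields <- list(); times <- numeric(0)
  next_release <- 0; next_output <- output_every_s
  t <- 0
  while (t < duration_s - 1e-9) {
    if (t >= next_release - 1e-9) {
      puffs <- release_puff(puffs, source,
                            source$emission_g_s * release_interval_s)
      next_release <- next_release + release_interval_s
    }
    w <- wind_at(t)
    puffs <- step_puffs(puffs, w[1], w[2], dt, spread_h, spread_z)
    t <- t + dt
    if (t >= next_output - 1e-9) {
      fields[[sprintf("t%06d", round(t))]] <-
        concentration_field(puffs, grid, spread_h, spread_z)
      times <- c(times, t)
      next_output <- next_output + output_every_s
    }
  }
  airborne <- sum(puffs$mass)
  deposited <- sum(puffs$deposited)
  structure(list(fields = fields, times = times, puffs = puffs,
                 deposited = deposited, airborne = airborne,
                 emitted = puffs$emitted,
                 mass_error = abs(puffs$emitted - airborne - deposited) /
                   max(puffs$emitted, .Machine$double.eps),
                 grid = grid),
            class = "dispersion_run")
}

#' @export
print.dispersion_run <- function(x, ...) {
  cat(sprintf(paste0("<dispersion_run: %d fields, emitted %.1f g, airborne ",
                     "%.1f g, deposited %.1f g, mass error %.2g>\n"),
              length(x$fields), x$emitted, x$airborne, x$deposited,
              x$mass_error))
  invisible(x)
}

#' Concentration time series at a receptor point
#'
#' @param run a `dispersion_run`.
#' @param x,y receptor coordinates, m (snapped to the nearest grid cell).
#' @return data.frame with `time_s` and `concentration_g_m3`.
#' @export
receptor_series <- function(run, x, y) {
  ix <- which.min(abs(run$grid$xs - x))
  iy <- which.min(abs(run$grid$ys - y))
  data.frame(time_s = run$times,
             concentration_g_m3 = vapply(run$fields, function(f) f[ix, iy], 1))
}

#' Write a concentration field as gridded CSV
#' @param field matrix from [concentration_field()].
#' @param grid the matching `dispersion_grid`.
#' @param file CSV path (columns x, y, value).
#' @export
write_field_csv <- function(field, grid, file) {
  d <- expand.grid(x = grid$xs, y = grid$ys)
  d$value <- as.vector(field)
  data.table::fwrite(d, file)
  invisible(file)
}
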