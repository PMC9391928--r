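#' Construct a batch of single-particle events
#'
#' An event batch is the column-oriented in-memory container for particles
#' detected by a single-particle laser spectrometer: one timestamp, one
#' optical diameter, one matrix per signal modality (elastic scattering
#' image, fluorescence spectrum, fluorescence lifetime) and an optional
#' class label per event.
#'
#' @param timestamps numeric vector, seconds from campaign start.
#' @param diameters numeric vector of optical diameters in micrometres;
#'   strictly positive.
#' @param signals named list of 3-D numeric arrays with dimensions
#'   `n x height x width`, one array per signal modality. May be an empty
#'   list for label-only batches.
#' @param labels optional character vector of class labels (`NA` allowed
#'   for unlabelled events).
#' @return an object of class `event_batch`.
#' @export
event_batch <- function(timestamps, diameters, signals = list(), labels = NULL) {
  n <- length(diameters)
  if (length(timestamps) != n)
    stopf("timestamps (%d) and diameters (%d) differ in length",
          length(timestamps), n)
  if (n > 0 && any(!is.finite(diameters)))
    stopf("all diameters must be finite")
  if (n > 0 && any(diameters <= 0))
    stopf("optical diameters must be > 0 (offending index %d)",
          which(diameters <= 0)[1L])
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (length(labels) != n)
    stopf("labels length (%d) does not match batch size (%d)", length(labels), n)
  if (length(signals)) {
    if (is.null(names(signals)) || any(!nzchar(names(signals))))
      stopf("signals must be a named list")
    for (nm in names(signals)) {
      a <- signals[[nm]]
      if (!is.array(a) || length(dim(a)) != 3L)
        stopf("signal '%s' must be a 3-D array (n x height x width)", nm)
      if (dim(a)[1L] != n)
        stopf("signal '%s' has %d rows but the batch has %d events",
              nm, dim(a)[1L], n)
      if (any(!is.finite(a)))
        stopf("signal '%s' contains non-finite values (offending event %d)",
              nm, which(apply(!is.finite(a), 1L, any))[1L])
    }
  }
  structure(list(timestamps = as.numeric(timestamps),
                 diameters = as.numeric(diameters),
                 signals = signals,
                 labels = labels),
            class = "event_batch")
}

#' Number of events in a batch
#' @param x an `event_batch`.
#' @param ... unused.
#' @export
length.event_batch <- function(x) length(x$diameters)

#' Subset an event batch by event index
#' @param x an `event_batch`.
#' @param i integer or logical index vector.
#' @param ... unused.
#' @export
`[.event_batch` <- function(x, i, ...) {
  sig <- lapply(x$signals, function(a) a[i, , , drop = FALSE])
  event_batch(x$timestamps[i], x$diameters[i], sig, x$labels[i])
}

#' @export
print.event_batch <- function(x, ...) {
  cat(sprintf("<event_batch: %d events, %d signal modalities (%s)>\n",
              length(x), length(x$signals),
              paste(names(x$signals), collapse = ", ")))
  lab <- x$labels[!is.na(x$labels)]
  if (length(lab)) {
    tab <- table(lab)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.event_batch <- function(x, ...) {
  data.frame(timestamp_s = x$timestamps, diameter_um = x$diameters,
             label = x$labels, stringsAsFactors = FALSE)
}

#' Size-gate an event batch by optical diameter
#'
#' Keeps exactly the events whose optical diameter is strictly greater than
#' the threshold, preserving order. The strict inequality mirrors the
#' instrument's particle gate (particles > 8 um in optical diameter);
#' boundary-equal diameters are excluded.
#'
#' @param batch an `event_batch`.
#' @param threshold_um gate threshold in micrometres, `>= 0`.
#' @return the filtered `event_batch`.
#' @export
filter_by_diameter <- function(batch, threshold_um = 8) {
  if (!inherits(batch, "event_batch")) stopf("batch must be an event_batch")
  if (!is_number(threshold_um) || threshold_um < 0)
    stopf("threshold_um must be a single number >= 0")
  batch[batch$diameters > threshold_um]
}

#' Tape length consumed by a drum sampler
#'
#' For a Hirst-type volumetric trap whose adhesive tape drum advances at a
#' constant speed, the tape section corresponding to a sampling duration is
#' simply speed times duration: 2 mm/h for 24 h gives the standard 48 mm
#' daily section, and 2 mm corresponds to one hourly sample.
#'
#' @param drum_speed_mm_h drum speed in mm per hour, `> 0`.
#' @param hours sampling duration in hours, `>= 0`.
#' @return tape length in mm.
#' @export
tape_length_for_duration <- function(drum_speed_mm_h, hours) {
  if (!is_number(drum_speed_mm_h) || drum_speed_mm_h <= 0)
    stopf("drum_speed_mm_h must be a single positive number")
  if (!is_number(hours) || hours < 0)
    stopf("hours must be a single non-negative number")
  drum_speed_mm_h * hours
}

#' Sampler specifications
#'
#' Constant specifications for the two co-located samplers: the Hirst-type
#' volumetric reference trap (10 L/min through a 2 x 14 mm orifice onto
#' tape moving 2 mm/h) and the laser spectrometer (2.8 L/min, counting
#' particles > 8 um optical diameter).
#'
#' @param name sampler name.
#' @param flow_rate_L_min air flow in litres per minute, `> 0`.
#' @param size_threshold_um lower optical-diameter bound of counted
#'   particles, `>= 0`.
#' @param drum_speed_mm_h tape drum speed (reference sampler only).
#' @param orifice_mm orifice dimensions c(width, height) in mm (reference
#'   sampler only).
#' @return a `sampler_spec` list.
#' @export
sampler_spec <- function(name, flow_rate_L_min, size_threshold_um = 0,
                         drum_speed_mm_h = NA_real_, orifice_mm = NULL) {
  if (!is_number(flow_rate_L_min) || flow_rate_L_min <= 0)
    stopf("flow_rate_L_min must be positive")
  if (!is_number(size_threshold_um) || size_threshold_um < 0)
    stopf("size_threshold_um must be >= 0")
  structure(list(name = name, flow_rate_L_min = flow_rate_L_min,
                 size_threshold_um = size_threshold_um,
                 drum_speed_mm_h = drum_speed_mm_h, orifice_mm = orifice_mm),
            class = "sampler_spec")
}

#' @rdname sampler_spec
#' @export
hirst_sampler <- function() {
  sampler_spec("hirst_volumetric", flow_rate_L_min = 10,
               size_threshold_um = 0, drum_speed_mm_h = 2,
               orifice_mm = c(2, 14))
}

#' @rdname sampler_spec
#' @export
laser_spectrometer <- function() {
  sampler_spec("laser_spectrometer", flow_rate_L_min = 2.8,
               size_threshold_um = 8)
}

#' Write / read an event batch
#'
#' Events are stored as a plain-text directory: a JSON sidecar
#' (`meta.json`) with the batch size, signal names and matrix dimensions,
#' an `events.csv` with timestamp, diameter and label columns, and one CSV
#' per signal modality holding the row-major flattened matrices (one event
#' per row). All numeric fields round-trip at full double precision.
#'
#' @param batch an `event_batch`.
#' @param path directory to create/read.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the `event_batch`.
#' @export
write_events <- function(batch, path) {
  if (!inherits(batch, "event_batch")) stopf("batch must be an event_batch")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(batch)
  meta <- list(n = n,
               signals = lapply(batch$signals, function(a) dim(a)[2:3]),
               class_names = sort(unique(batch$labels[!is.na(batch$labels)])))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  # %.17g guarantees bit-exact double round-trips through text
  data.table::fwrite(
    data.table::data.table(timestamp_s = sprintf("%.17g", batch$timestamps),
                           diameter_um = sprintf("%.17g", batch$diameters),
                           label = batch$labels),
    file.path(path, "events.csv"))
  for (nm in names(batch$signals)) {
    a <- batch$signals[[nm]]
    m <- matrix(as.vector(aperm(a, c(3, 2, 1))), nrow = n, byrow = TRUE)
    mm <- matrix(sprintf("%.17g", m), nrow = n)
    data.table::fwrite(data.table::as.data.table(mm),
                       file.path(path, paste0("signal_", nm, ".csv")))
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("no event container at '%s'", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ev <- data.table::fread(file.path(path, "events.csv"),
                          colClasses = list(character = "label"))
  n <- meta$n
  signals <- list()
  for (nm in names(meta$signals)) {
    d <- as.integer(meta$signals[[nm]])
    m <- as.matrix(data.table::fread(
      file.path(path, paste0("signal_", nm, ".csv"))))
    if (n > 0 && (nrow(m) != n || ncol(m) != prod(d)))
      stopf("signal '%s': stored shape %dx%d inconsistent with meta (%d events, %dx%d)",
            nm, nrow(m), ncol(m), n, d[1], d[2])
    a <- array(NA_real_, c(n, d[1], d[2]))
    if (n > 0)
      a <- aperm(array(t(m), c(d[2], d[1], n)), c(3, 2, 1))
    signals[[nm]] <- a
  }
  labels <- if (n > 0) as.character(ev$label) else character(0)
  labels[!is.na(labels) & labels == ""] <- NA_character_
  event_batch(if (n > 0) ev$timestamp_s else numeric(0),
              if (n > 0) ev$diameter_um else numeric(0),
              signals, labels)
}

#' Export event scalars to CSV for inspection
#' @param batch an `event_batch`.
#' @param file output CSV path.
#' @export
export_events_csv <- function(batch, file) {
  data.table::fwrite(as.data.frame(batch), file)
  invisible(file)
}
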