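# Mean-signal templates per particle class.
#
# Each class gets one mean matrix per signal modality, built as a sum of a
# few smooth Gaussian bumps at seeded random positions, plus a lognormal
# optical-diameter distribution. Bump fields are a deliberately simple
# stand-in for instrument responses: smooth, non-negative, peak amplitude
# near 1, and pairwise well separated in L2.

default_signal_dims <- function() {
  list(scattering = c(24L, 40L), spectrum = c(32L, 8L), lifetime = c(4L, 64L))
}

# smooth non-negative random field: sum of `k` Gaussian bumps
random_bump_field <- function(h, w, k = 3L) {
  f <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(k)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    sy <- stats::runif(1, h / 10, h / 3); sx <- stats::runif(1, w / 10, w / 3)
    amp <- stats::runif(1, 0.5, 1)
    f <- f + amp * exp(-((rows - cy)^2 / (2 * sy^2) +
                           (cols - cx)^2 / (2 * sx^2)))
  }
  f
}

#' Generate per-class mean-signal templates
#'
#' Builds one mean scattering matrix, fluorescence-spectrum matrix and
#' fluorescence-lifetime matrix per class, plus a per-class lognormal
#' optical-diameter distribution. Templates are deterministic in `seed` and
#' pairwise distinguishable: the minimum pairwise L2 distance between the
#' concatenated class mean signals must exceed `separation_floor` (fields
#' are redrawn, still deterministically, until it does).
#'
#' The starch class is given a diameter distribution with median 12 um
#' (spread 0.25 on the log scale) so that most granules pass the > 8 um
#' optical gate; other classes get seeded medians between 10 and 30 um.
#'
#' @param classes character vector of class names (>= 2, unique).
#' @param signal_dims named list of `c(height, width)` per signal modality.
#' @param seed integer seed.
#' @param separation_floor minimum pairwise L2 distance between class
#'   mean signals (concatenated across modalities).
#' @return a `class_templates` object: per class, a list of mean matrices
#'   (one per modality) and diameter distribution parameters
#'   `meanlog`/`sdlog`.
#' @export
generate_class_templates <- function(classes,
                                     signal_dims = default_signal_dims(),
                                     seed = 1L,
                                     separation_floor = 1) {
  classes <- as.character(classes)
  if (length(classes) < 2L) stopf("need at least 2 classes")
  if (anyDuplicated(classes))
    stopf("duplicate class names: %s",
          paste(unique(classes[duplicated(classes)]), collapse = ", "))
  if (!length(signal_dims) || is.null(names(signal_dims)))
    stopf("signal_dims must be a named list of c(height, width)")
  for (nm in names(signal_dims)) {
    d <- signal_dims[[nm]]
    if (length(d) != 2L || any(d < 1))
      stopf("signal_dims[['%s']] must be two positive integers", nm)
  }
  for (attempt in 0:49) {
    tpl <- with_seed(derive_seed(seed, attempt), {
      out <- lapply(classes, function(cl) {
        sig <- lapply(signal_dims, function(d)
          random_bump_field(d[1L], d[2L]))
        med <- if (identical(cl, "starch")) 12 else stats::runif(1, 10, 30)
        list(signals = sig,
             diameter = list(meanlog = log(med),
                             sdlog = if (identical(cl, "starch")) 0.25 else 0.3))
      })
      names(out) <- classes
      out
    })
    if (min_template_distance(tpl) > separation_floor) {
      return(structure(list(classes = classes,
                            signal_dims = lapply(signal_dims, as.integer),
                            templates = tpl,
                            seed = seed),
                       class = "class_templates"))
    }
  }
  stopf("could not reach separation floor %.3g after 50 draws", separation_floor)
}

# minimum pairwise L2 distance between concatenated class mean signals
min_template_distance <- function(tpl) {
  vecs <- lapply(tpl, function(t) unlist(t$signals, use.names = FALSE))
  k <- length(vecs)
  dmin <- Inf
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    dmin <- min(dmin, sqrt(sum((vecs[[i]] - vecs[[j]])^2)))
  dmin
}

#' @export
print.class_templates <- function(x, ...) {
  cat(sprintf("<class_templates: %d classes (%s); min pairwise L2 = %.2f>\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              min_template_distance(x$templates)))
  invisible(x)
}
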