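#' Otsu global threshold of an image
#'
#' Classic histogram-based global thresholding: the image range is split
#' into `n_bins` equal bins and the returned threshold is the internal bin
#' edge that maximises the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, with class statistics computed from bin
#' midpoints. Ties break toward the lower threshold. A constant image has
#' no two classes and is a degenerate-image error.
#'
#' @param image A [pam_map()], matrix, or numeric vector.
#' @param n_bins Number of histogram bins.
#' @return Scalar threshold (a bin edge).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- if (inherits(image, "pam_map")) as.numeric(image$values)
       else as.numeric(image)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    pam_abort("degenerate image: all values identical, Otsu undefined",
              "degenerate_image")
  }
  n_bins <- as.integer(n_bins)
  w <- diff(rng) / n_bins
  cnt <- if (length(v) > 1e6) {
    cpp_bincount(v, rng[1], w, n_bins)
  } else {
    tabulate(pmin(floor((v - rng[1]) / w) + 1, n_bins), n_bins)
  }
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * w
  n <- length(v)
  cw <- cumsum(cnt)
  cm <- cumsum(cnt * mids)
  total_mean <- cm[n_bins] / n
  k <- seq_len(n_bins - 1)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
  mu1 <- ifelse(cw[k] < n, (cm[n_bins] - cm[k]) / (n - cw[k]), total_mean)
  between <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(between) # first max = lower threshold on ties
  rng[1] + best * w
}

#' Shared threshold for a timepoint series of MAP images
#'
#' The images of one subject/layer series view the same location, so a
#' single global threshold is applied to all of them: the arithmetic mean
#' of the per-image Otsu thresholds. A degenerate image in the series is
#' reported with its index.
#'
#' @param maps List of [pam_map()]s (or matrices) from one series.
#' @param n_bins Histogram bins for each Otsu threshold.
#' @return Scalar series threshold.
#' @export
series_threshold <- function(maps, n_bins = 256L) {
  if (length(maps) < 2) {
    pam_abort("a series needs at least 2 MAP images", "invalid_series")
  }
  shapes <- vapply(maps, function(m) {
    v <- if (inherits(m, "pam_map")) m$values else m
    paste(dim(v), collapse = "x")
  }, character(1))
  if (length(unique(shapes)) != 1) {
    pam_abort("MAP images in a series must share one shape", "invalid_series")
  }
  layers <- vapply(maps, function(m) {
    if (inherits(m, "pam_map")) m$layer else NA_character_
  }, character(1))
  if (length(unique(stats::na.omit(layers))) > 1) {
    pam_abort("MAP images in a series must share one layer", "invalid_series")
  }
  thr <- vapply(seq_along(maps), function(i) {
    tryCatch(otsu_threshold(maps[[i]], n_bins = n_bins),
             pamvasc_degenerate_image = function(e) {
               pam_abort(paste0("degenerate MAP image at series index ", i),
                         "degenerate_image")
             })
  }, numeric(1))
  mean(thr)
}

#' Vascular density of a MAP image
#'
#' The number of pixels with value strictly greater than the threshold.
#'
#' @param map A [pam_map()] or matrix.
#' @param threshold Finite scalar threshold.
#' @return Integer pixel count.
#' @export
vascular_density <- function(map, threshold) {
  if (!is.finite(threshold)) pam_abort("threshold must be finite", "invalid_threshold")
  v <- if (inherits(map, "pam_map")) map$values else map
  sum(v > threshold)
}

#' Relative density trace of one subject/layer series
#'
#' Normalises the per-timepoint densities by the first timepoint
#' (`t = 0`) and reports the constriction percentage
#' `100 * (1 - relative)` at the final timepoint.
#'
#' @param density Integer densities, one per timepoint.
#' @param t_min Timepoints in minutes (first must be 0).
#' @param subject_id,group,layer Provenance labels.
#' @param threshold The series threshold used.
#' @return Tibble with one row per timepoint: `subject_id`, `group`,
#'   `layer`, `t_min`, `density`, `relative`, `threshold`; the final
#'   constriction is available via [trace_constriction()].
#' @export
relative_trace <- function(density, t_min, subject_id = NA_character_,
                           group = NA_character_, layer = "WHOLE",
                           threshold = NA_real_) {
  stopifnot(length(density) == length(t_min))
  ord <- order(t_min)
  density <- density[ord]
  t_min <- t_min[ord]
  if (t_min[1] != 0) pam_abort("trace must start at t = 0", "invalid_trace")
  if (density[1] <= 0) {
    pam_abort("undefined baseline: density at t = 0 is zero",
              "undefined_baseline")
  }
  tibble::tibble(subject_id = subject_id, group = group, layer = layer,
                 t_min = t_min, density = as.integer(density),
                 relative = density / density[1], threshold = threshold)
}

#' Final-timepoint constriction of density traces
#'
#' @param traces A trace tibble (possibly many subjects/layers/groups).
#' @return Tibble with one row per `subject_id` x `group` x `layer`:
#'   `constriction_pct = 100 * (1 - relative at the final timepoint)`.
#' @export
trace_constriction <- function(traces) {
  traces |>
    dplyr::group_by(.data$subject_id, .data$group, .data$layer) |>
    dplyr::summarise(
      constriction_pct = 100 * (1 - .data$relative[which.max(.data$t_min)]),
      .groups = "drop")
}

#' Depth centroid of the vascular network
#'
#' Mean depth (micrometres below the surface) of the suprathreshold voxels
#' of a flattened volume. Unweighted by default; `weighted = TRUE` weights
#' each voxel by its amplitude.
#'
#' @param flat A flattened [pam_volume()].
#' @param threshold Voxel threshold; `NULL` computes Otsu over the volume.
#' @param min_depth_um Exclude voxels shallower than this (e.g. to mask a
#'   surface signal).
#' @param weighted Amplitude-weighted centroid.
#' @return Centroid depth in micrometres.
#' @export
centroid_depth <- function(flat, threshold = NULL, min_depth_um = 0,
                           weighted = FALSE) {
  amp <- flat$amplitude
  d <- dim(amp)
  dz <- flat$spacing_um[3]
  thr <- threshold %||% otsu_threshold(as.numeric(amp))
  depth <- (seq_len(d[3]) - 1) * dz
  keep <- depth >= min_depth_um
  per_z <- if (weighted) {
    m <- matrix(amp, d[1] * d[2], d[3])
    colSums(m * (m > thr))
  } else {
    cpp_depth_counts(as.numeric(amp), d, thr)
  }
  per_z[!keep] <- 0
  tot <- sum(per_z)
  if (tot == 0) {
    pam_abort("no suprathreshold voxels: centroid undefined", "empty_mask")
  }
  sum(per_z * depth) / tot
}
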