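#' Depth histogram of vessel voxels
#'
#' Counts, per depth index of a flattened volume, the voxels whose
#' amplitude exceeds a global threshold (Otsu over all voxel amplitudes by
#' default). The counts are also smoothed with a moving average whose
#' window defaults to one axial PSF width, since peak picking on raw
#' counts is unstable.
#'
#' @param flat A flattened [pam_volume()].
#' @param threshold Voxel threshold; `NULL` computes Otsu over the volume.
#' @param smooth_window Moving-average window in samples; `NULL` uses
#'   `round(smooth_window_um / dz)` forced odd.
#' @param smooth_window_um Window expressed in micrometres (default one
#'   axial PSF width, 30 um).
#' @param n_bins Histogram bins for the Otsu threshold.
#' @return Object of class `pam_depth_histogram` with `counts`,
#'   `smoothed`, `depth_um`, and the `threshold` used.
#' @export
depth_histogram <- function(flat, threshold = NULL, smooth_window = NULL,
                            smooth_window_um = 30, n_bins = 256L) {
  amp <- flat$amplitude
  d <- dim(amp)
  dz <- flat$spacing_um[3]
  thr <- threshold %||% otsu_threshold(as.numeric(amp), n_bins = n_bins)
  counts <- cpp_depth_counts(as.numeric(amp), d, thr)
  win <- smooth_window %||% max(1L, round(smooth_window_um / dz))
  win <- as.integer(win)
  if (win %% 2 == 0) win <- win + 1L
  smoothed <- if (win > 1) moving_average(counts, win) else counts
  structure(list(counts = counts, smoothed = smoothed,
                 depth_um = (seq_len(d[3]) - 1) * dz,
                 threshold = thr, dz = dz, smooth_window = win),
            class = "pam_depth_histogram")
}

# centered moving average with shrinking window at the edges
moving_average <- function(x, win) {
  n <- length(x)
  half <- win %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.pam_depth_histogram <- function(x, ...) {
  cat(sprintf(
    "<pam_depth_histogram> %d depths (dz %g um), threshold %.4g, %d vessel voxels\n",
    length(x$counts), x$dz, x$threshold, sum(x$counts)))
  invisible(x)
}

#' @method tidy pam_depth_histogram
#' @export
tidy.pam_depth_histogram <- function(x, ...) {
  tibble::tibble(depth_um = x$depth_um, count = x$counts,
                 smoothed = x$smoothed)
}

#' Locate the papillary and hypodermal histogram peaks
#'
#' Finds interior local maxima of the smoothed depth histogram, ranks them
#' by topographic prominence, and greedily keeps peaks at least
#' `min_separation_um` apart; the two most prominent survivors, ordered
#' shallow-first, are taken as the papillary-plexus and hypodermal-plexus
#' depths. Fewer than two admissible peaks is a segmentation error that
#' reports the number found.
#'
#' @param hist A [depth_histogram()].
#' @param min_separation_um Minimum depth separation between the two peaks.
#' @param min_depth_um Ignore candidate peaks shallower than this (useful
#'   when a bright surface/epidermis signal is present).
#' @return List with `d_pd`, `d_hd` (1-based depth indices), `depth_um`,
#'   and the candidate table.
#' @export
find_layer_peaks <- function(hist, min_separation_um = 100,
                             min_depth_um = 0) {
  s <- hist$smoothed
  if (all(s == 0)) {
    pam_abort("segmentation error: depth histogram is identically zero",
              "segmentation")
  }
  cand <- local_maxima(s)
  cand <- cand[hist$depth_um[cand] >= min_depth_um]
  prom <- peak_prominence(s, cand)
  ord <- order(prom, decreasing = TRUE)
  cand <- cand[ord]
  prom <- prom[ord]
  sep <- max(1L, round(min_separation_um / hist$dz))
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(p - keep) >= sep)) keep <- c(keep, p)
    if (length(keep) == 2) break
  }
  if (length(keep) < 2) {
    pam_abort(sprintf(
      "segmentation error: found %d admissible histogram peak(s), need 2",
      length(keep)), "segmentation")
  }
  keep <- sort(keep)
  list(d_pd = keep[1], d_hd = keep[2],
       depth_um = hist$depth_um[keep],
       candidates = tibble::tibble(index = cand,
                                   depth_um = hist$depth_um[cand],
                                   prominence = prom))
}

# interior local maxima; plateaus contribute their first index
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  idx
}

# topographic prominence: height above the higher of the two side minima,
# where each side extends to the nearest strictly higher point (or edge)
peak_prominence <- function(s, peaks) {
  vapply(peaks, function(p) {
    h <- s[p]
    i <- p - 1L
    lmin <- h
    while (i >= 1 && s[i] <= h) {
      if (s[i] < lmin) lmin <- s[i]
      i <- i - 1L
    }
    j <- p + 1L
    rmin <- h
    while (j <= length(s) && s[j] <= h) {
      if (s[j] < rmin) rmin <- s[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Segment the depth axis into PD / RD / HD slabs
#'
#' Given the two histogram peaks, slab boundaries are placed either at the
#' least-count depths between each peak and their midpoint (`"valleys"`,
#' the default: ties resolve to the centre of the minimal plateau) or at
#' the peaks themselves (`"peaks"`, the literal peaks-as-separators
#' reading). The papillary slab runs from the surface through the first
#' boundary, the hypodermal slab from the second boundary down, and the
#' reticular slab between (half-open). An empty reticular slab is an error
#' suggesting the alternative rule.
#'
#' The avascular epidermis occupies the top of the flattened volume (and,
#' when a surface signal is present, glows); `epidermis_um` sets the depth
#' at which the papillary slab starts, excluding that zone from every
#' layer map.
#'
#' @param hist A [depth_histogram()].
#' @param peaks Result of [find_layer_peaks()]; computed if `NULL`.
#' @param rule `"valleys"` or `"peaks"`.
#' @param epidermis_um Depth below the detected surface at which vascular
#'   tissue starts; the PD and WHOLE slabs begin here.
#' @param ... Passed to [find_layer_peaks()] when `peaks` is `NULL`.
#' @return Object of class `pam_layer_boundaries`.
#' @export
segment_layers <- function(hist, peaks = NULL,
                           rule = c("valleys", "peaks"),
                           epidermis_um = 0, ...) {
  rule <- match.arg(rule)
  peaks <- peaks %||% find_layer_peaks(hist, ...)
  d_pd <- peaks$d_pd
  d_hd <- peaks$d_hd
  if (d_pd >= d_hd) pam_abort("peaks must satisfy d_pd < d_hd", "segmentation")
  if (d_hd - d_pd < 2) {
    pam_abort(paste0(
      "degenerate segmentation: adjacent peaks leave an empty reticular ",
      "slab (indices ", d_pd, ", ", d_hd, ")"), "segmentation")
  }
  if (rule == "peaks") {
    z1 <- d_pd
    z2 <- d_hd
  } else {
    s <- hist$smoothed
    mid <- floor((d_pd + d_hd) / 2)
    z1 <- plateau_argmin(s, (d_pd + 1L):mid)
    z2 <- plateau_argmin(s, mid:(d_hd - 1L))
  }
  nz <- length(hist$counts)
  z_ed <- min(max(1L, as.integer(round(epidermis_um / hist$dz)) + 1L), nz)
  if (z_ed > z1) {
    pam_abort(paste0("epidermis exclusion (", epidermis_um,
                     " um) swallows the papillary slab"), "segmentation")
  }
  if (z2 - z1 < 2) {
    pam_abort(paste0(
      "degenerate segmentation: reticular slab is empty (boundaries ", z1,
      ", ", z2, "); try the alternative boundary rule"), "segmentation")
  }
  structure(list(d_pd = d_pd, d_hd = d_hd, z_pd_rd = z1, z_rd_hd = z2,
                 z_ed = z_ed, epidermis_um = epidermis_um,
                 rule = rule, dz = hist$dz, nz = nz),
            class = "pam_layer_boundaries")
}

# index of the minimum over idx; ties -> centre of the minimal plateau
plateau_argmin <- function(s, idx) {
  v <- s[idx]
  at <- idx[v == min(v)]
  at[ceiling(length(at) / 2)]
}

#' @export
print.pam_layer_boundaries <- function(x, ...) {
  um <- function(i) (i - 1) * x$dz
  cat(sprintf(
    "<pam_layer_boundaries> rule '%s': peaks %g/%g um; PD [%g, %g], RD (%g, %g), HD [%g, %g) um\n",
    x$rule, um(x$d_pd), um(x$d_hd), um(x$z_ed %||% 1), um(x$z_pd_rd),
    um(x$z_pd_rd), um(x$z_rd_hd), um(x$z_rd_hd), um(x$nz)))
  invisible(x)
}

# 1-based inclusive depth index range of a layer slab
layer_slab <- function(bounds, layer) {
  z_ed <- bounds$z_ed %||% 1L
  switch(layer,
    PD = c(z_ed, bounds$z_pd_rd),
    RD = c(bounds$z_pd_rd + 1L, bounds$z_rd_hd - 1L),
    HD = c(bounds$z_rd_hd, bounds$nz),
    WHOLE = c(z_ed, bounds$nz),
    pam_abort(paste0("unknown layer tag: ", layer), "unknown_layer"))
}

#' Layer-wise maximum-amplitude projection
#'
#' Pixelwise maximum of the flattened volume over the layer's depth slab
#' (`"WHOLE"` projects the full depth range). The three layer slabs tile
#' the depth axis exactly once, so the pixelwise max of the PD, RD, and HD
#' maps reproduces the WHOLE map.
#'
#' @param flat A flattened [pam_volume()].
#' @param bounds A [segment_layers()] result.
#' @param layer `"PD"`, `"RD"`, `"HD"`, or `"WHOLE"`.
#' @return A [pam_map()].
#' @export
layer_map <- function(flat, bounds, layer) {
  slab <- layer_slab(bounds, layer)
  d <- dim(flat$amplitude)
  vals <- cpp_max_project_z(as.numeric(flat$amplitude), d, slab[1], slab[2])
  pam_map(vals, layer = layer, t_min = flat$t_min,
          subject_id = flat$subject_id, group = flat$group)
}

#' Cross-sectional projection along Y (B-scan view)
#'
#' Pixelwise maximum over the Y axis, giving an `(x, z)` image that shows
#' the vascular stratification with depth.
#'
#' @param volume A [pam_volume()] (raw or flattened).
#' @return Numeric matrix `(x, z)` with the volume's spacing as an
#'   attribute.
#' @export
b_scan_map <- function(volume) {
  d <- dim(volume$amplitude)
  out <- cpp_max_project_y(as.numeric(volume$amplitude), d)
  attr(out, "spacing_um") <- volume$spacing_um[c(1, 3)]
  out
}
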