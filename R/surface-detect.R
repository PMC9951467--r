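#' Detect the skin surface per A-line
#'
#' For every A-line the surface estimate is the shallowest depth index at
#' which the amplitude reaches `frac` times that A-line's maximum. A-lines
#' whose maximum falls below a global noise floor carry no surface
#' information and are filled by interpolation from their neighbours.
#' Because the first strong absorber on an A-line may be a deep vessel
#' rather than the shallow plexus, detections much deeper than the robust
#' field median (beyond `outlier_mad` scaled MADs) are rejected and filled
#' the same way. The filled field is finally smoothed with a 2-D median
#' filter, which suppresses heartbeat/respiration-like spike artifacts.
#'
#' @param volume A [pam_volume()] (raw, unflattened).
#' @param frac Per-A-line threshold fraction in `(0, 1)`.
#' @param noise_floor Absolute amplitude floor below which an A-line is
#'   considered empty; default `0.2 * max(amplitude)`.
#' @param median_window Side of the square median filter window (odd).
#' @param outlier_mad Reject detections deeper than
#'   `median + outlier_mad * mad` (set `NULL` to disable).
#' @return Object of class `pam_surface`: fractional 1-based surface depth
#'   indices over the lateral grid.
#' @export
detect_surface <- function(volume, frac = 0.5, noise_floor = NULL,
                           median_window = 11L, outlier_mad = 3.5) {
  stopifnot(frac > 0, frac < 1)
  amp <- volume$amplitude
  d <- dim(amp)
  floor_abs <- noise_floor %||% (0.2 * max(amp))
  raw <- cpp_first_crossing(as.numeric(amp), d, frac, floor_abs)
  if (all(is.na(raw))) {
    pam_abort("no surface: volume is entirely below the noise floor",
              "no_surface")
  }
  if (!is.null(outlier_mad)) {
    med <- median(raw, na.rm = TRUE)
    spread <- stats::mad(raw, na.rm = TRUE)
    cut <- med + max(outlier_mad * spread, 2)
    raw[raw > cut] <- NA
  }
  filled <- fill_na_neighbors(raw)
  win <- min(as.integer(median_window), max(d[1], d[2]))
  if (win %% 2 == 0) win <- win + 1L
  sm <- cpp_median_filter2d(filled, win)
  sm <- pmin(pmax(sm, 1), d[3])
  structure(list(z_index = sm, dim = d[1:2],
                 spacing_um = volume$spacing_um),
            class = "pam_surface")
}

#' @export
print.pam_surface <- function(x, ...) {
  cat(sprintf("<pam_surface> %d x %d, depth %g-%g um\n",
              x$dim[1], x$dim[2],
              round(min(x$z_index - 1) * x$spacing_um[3], 1),
              round(max(x$z_index - 1) * x$spacing_um[3], 1)))
  invisible(x)
}

# iterative fill of NA cells from the mean of available 3x3 neighbours
fill_na_neighbors <- function(m) {
  if (!anyNA(m)) return(m)
  nx <- nrow(m)
  ny <- ncol(m)
  box3 <- function(x) {
    p <- matrix(0, nx + 2, ny + 2)
    p[2:(nx + 1), 2:(ny + 1)] <- x
    r <- matrix(0, nx, ny)
    for (di in 0:2) for (dj in 0:2) {
      r <- r + p[di + seq_len(nx), dj + seq_len(ny), drop = FALSE]
    }
    r
  }
  repeat {
    na <- is.na(m)
    if (!any(na)) break
    vals <- m
    vals[na] <- 0
    s <- box3(vals)
    cnt <- box3((!na) * 1)
    grow <- na & cnt > 0
    if (!any(grow)) break # fully NA (cannot happen after the floor check)
    m[grow] <- s[grow] / cnt[grow]
  }
  m
}

#' Flatten a volume to surface-referenced depth
#'
#' Shifts every A-line by linear interpolation so that its surface index
#' lands at depth index 1; depth in the result means depth below the skin
#' surface. Values shifted in from beyond the original grid are 0.
#'
#' @param volume A [pam_volume()].
#' @param surface A [pam_surface()] with matching lateral shape.
#' @return A flattened [pam_volume()].
#' @export
flatten <- function(volume, surface) {
  d <- dim(volume$amplitude)
  zi <- if (inherits(surface, "pam_surface")) surface$z_index else surface
  if (!all(dim(zi) == d[1:2])) {
    pam_abort("surface lateral shape does not match the volume", "shape_mismatch")
  }
  flat <- cpp_flatten(as.numeric(volume$amplitude), d, zi)
  # interpolation of non-negative values stays non-negative: skip revalidation
  structure(list(amplitude = array(flat, d),
                 spacing_um = volume$spacing_um, t_min = volume$t_min,
                 subject_id = volume$subject_id, group = volume$group,
                 flattened = TRUE), class = "pam_volume")
}
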