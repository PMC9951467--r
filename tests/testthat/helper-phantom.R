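# small fixtures shared across tests; all generated in code at test time

# a fast phantom for unit tests: coarse field, few vessels, full depth
# structure (papillary band, connectors, one hypodermal pair)
tiny_spec <- function(...) {
  args <- list(nx = 64L, ny = 64L, nz = 230L,
               surface_mean_um = 45, surface_amplitude_um = 20,
               n_pd = 4L, pd_radius_um = c(20, 30),
               pd_depth_um = 90, pd_depth_sd_um = 6,
               n_rd = 4L, rd_radius_um = c(12, 18), rd_drift_um = 80,
               n_hd_pairs = 1L, hd_radius_um = c(25, 35),
               hd_depth_um = 450, hd_depth_sd_um = 10)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantom_spec, args)
}

flat_surface <- function(spec) matrix(spec$surface_mean_um, spec$nx, spec$ny)

# a single straight horizontal tube along y at the given skin depth
straight_tube <- function(spec, depth_um, radius_um, x_um = NULL,
                          layer = "PD", intensity = 1) {
  Y <- (spec$ny - 1) * spec$spacing_um[2]
  x <- x_um %||% ((spec$nx - 1) * spec$spacing_um[1] / 2)
  tibble::tibble(
    vessel_id = 1L, layer = layer, radius_um = radius_um,
    intensity = intensity,
    centerline = list(cbind(c(x, x), c(0, Y), c(depth_um, depth_um))))
}

# depth histogram object built directly from counts (for peak-finding tests)
make_hist <- function(counts, dz = 1, smooth_window = 1L) {
  structure(list(counts = counts, smoothed = counts,
                 depth_um = (seq_along(counts) - 1) * dz,
                 threshold = 0, dz = dz, smooth_window = smooth_window),
            class = "pam_depth_histogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
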