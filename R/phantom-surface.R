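#' Generate the undulating skin surface of a phantom
#'
#' The surface is a smooth Gaussian random field: lateral white noise
#' smoothed with a Gaussian kernel of standard deviation equal to half the
#' requested correlation length (so the field autocorrelation drops to 1/e
#' at approximately that length), recentred on the mean depth and rescaled
#' so the maximum absolute undulation equals `surface_amplitude_um`.
#' Amplitude 0 yields a perfectly flat surface.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed controlling the realisation; defaults to `spec$seed`.
#' @return An `nx` x `ny` matrix of surface depths in micrometres below the
#'   grid top.
#' @export
generate_surface <- function(spec, seed = spec$seed) {
  nx <- spec$nx
  ny <- spec$ny
  if (spec$surface_amplitude_um == 0) {
    return(matrix(spec$surface_mean_um, nx, ny))
  }
  field <- withr::with_seed(seed, matrix(rnorm(nx * ny), nx, ny))
  sigma_um <- spec$surface_corr_um / 2
  sigma_vox <- c(sigma_um / spec$spacing_um[1], sigma_um / spec$spacing_um[2], 0)
  sm <- cpp_gauss_blur3d(as.numeric(field), c(nx, ny, 1L), sigma_vox)
  sm <- matrix(sm, nx, ny)
  sm <- sm - mean(sm)
  m <- max(abs(sm))
  if (m > 0) sm <- sm * (spec$surface_amplitude_um / m)
  surf <- sm + spec$surface_mean_um
  if (min(surf) < 0 || max(surf) >= spec$nz * spec$spacing_um[3]) {
    pam_abort("surface undulation leaves the grid", "invalid_spec")
  }
  surf
}
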