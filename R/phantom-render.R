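#' Render a phantom scene into a PA amplitude volume
#'
#' Voxel amplitude is the maximum over vessels of the tube indicator
#' (distance to centerline below the radius) times the vessel intensity,
#' with depths shifted by the local surface so that the anatomy follows the
#' skin profile. The scene is then convolved with an anisotropic Gaussian
#' point-spread function (sigma = FWHM / 2.3548 per axis) and corrupted by
#' additive Gaussian noise clipped at zero. Both steps can be disabled for
#' geometric tests.
#'
#' @param vessels Vessel tibble from [place_vessels()] (possibly after
#'   [apply_constriction()]).
#' @param surface Surface matrix from [generate_surface()].
#' @param spec The [phantom_spec()].
#' @param t_min Acquisition time stamped on the volume.
#' @param psf,noise Logical switches for the PSF blur and the noise.
#' @param noise_seed Seed for the noise draw; defaults to a value derived
#'   from `spec$seed` and `t_min` so repeated renders are bit-identical.
#' @param subject_id,group Provenance stamped on the volume.
#' @return A [pam_volume()].
#' @export
render_volume <- function(vessels, surface, spec, t_min = 0,
                          psf = TRUE, noise = TRUE, noise_seed = NULL,
                          subject_id = NA_character_, group = NA_character_) {
  dim3 <- c(spec$nx, spec$ny, spec$nz)
  if (is.null(noise_seed)) {
    noise_seed <- (spec$seed + 7919L * (round(t_min) + 1L)) %% 2147483647L
  }
  jitter <- spec$motion_jitter_um %||% 0
  if (jitter > 0) {
    # one displacement per B-scan (constant along x, drawn per y row)
    dz_row <- withr::with_seed(noise_seed + 1L,
                               rnorm(spec$ny, 0, jitter))
    surface <- sweep(surface, 2, dz_row, "+")
    surface <- pmin(pmax(surface, 0),
                    (spec$nz - 1) * spec$spacing_um[3])
  }
  amp <- cpp_render_tubes(
    dim3, spec$spacing_um,
    lapply(vessels$centerline, function(m) m[, 1:3, drop = FALSE]),
    as.numeric(vessels$radius_um), as.numeric(vessels$intensity),
    surface, spec$epidermis_intensity, spec$epidermis_thickness_um)
  if (psf) {
    sigma_vox <- c(spec$psf_fwhm_um[1] / spec$spacing_um[1],
                   spec$psf_fwhm_um[1] / spec$spacing_um[2],
                   spec$psf_fwhm_um[2] / spec$spacing_um[3]) / 2.3548
    amp <- cpp_gauss_blur3d(amp, dim3, sigma_vox)
  }
  if (noise && spec$noise_sd > 0) {
    eps <- withr::with_seed(noise_seed, rnorm(prod(dim3), 0, spec$noise_sd))
    amp <- cpp_add_clip(amp, eps)
  }
  pam_volume(amp, spacing_um = spec$spacing_um, t_min = t_min,
             subject_id = subject_id, group = group)
}

#' Simulate one subject's acquisition series
#'
#' Draws a surface and a baseline vessel set, then renders one volume per
#' timepoint with the group's constriction schedules applied. The returned
#' bundle carries the subject's analytic ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param schedules Named list of per-layer [constriction_schedule()]s.
#' @param subject_id,group Provenance labels.
#' @param seed Master seed for this subject (surface, vessels, and noise
#'   derive from it deterministically).
#' @return List with `volumes` (list of [pam_volume()], one per timepoint),
#'   `surface`, `vessels` (baseline), and `truth` (a [phantom_truth()]).
#' @export
simulate_subject <- function(spec, schedules = list(),
                             subject_id = "s1", group = "control",
                             seed = spec$seed) {
  surface <- generate_surface(spec, seed = seed)
  vessels <- place_vessels(spec, seed = seed + 1L)
  volumes <- lapply(seq_along(spec$timepoints_min), function(i) {
    t <- spec$timepoints_min[i]
    vt <- apply_constriction(vessels, schedules, t)
    render_volume(vt, surface, spec, t_min = t,
                  noise_seed = (seed + 211L * i) %% 2147483647L,
                  subject_id = subject_id, group = group)
  })
  list(volumes = volumes, surface = surface, vessels = vessels,
       truth = phantom_truth(spec, vessels, schedules))
}

# deterministic per-subject seed derived from the master seed
subject_seed <- function(master_seed, group_index, subject_index) {
  as.integer((as.numeric(master_seed) %% 1e6 * 1009 +
                group_index * 7907 + subject_index * 131) %% 2147483647)
}
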