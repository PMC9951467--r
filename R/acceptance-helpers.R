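#' Measured constriction versus the geometric oracle
#'
#' Joins a phantom study's measured per-subject constriction with the
#' projected-area oracle evaluated at the final timepoint and summarises
#' the deviation per group and layer.
#'
#' @param study A `pam_study` run with `with_truth = TRUE`.
#' @return Tibble: `group`, `layer`, `measured_pct`, `truth_pct`,
#'   `deviation_pct` (means over subjects), `n`.
#' @export
constriction_vs_truth <- function(study) {
  if (is.null(study$truth)) {
    pam_abort("study carries no ground truth (with_truth = FALSE?)",
              "no_truth")
  }
  t_final <- max(study$truth$t_min)
  tcon <- study$truth |>
    dplyr::filter(.data$t_min == t_final) |>
    dplyr::transmute(.data$group, .data$subject_id, .data$layer,
                     truth_pct = 100 * (1 - .data$truth_relative))
  study$constriction |>
    dplyr::inner_join(tcon, by = c("group", "subject_id", "layer")) |>
    dplyr::group_by(.data$group, .data$layer) |>
    dplyr::summarise(measured_pct = mean(.data$constriction_pct),
                     truth_pct = mean(.data$truth_pct),
                     deviation_pct = .data$measured_pct - .data$truth_pct,
                     n = dplyr::n(), .groups = "drop")
}

#' Qualitative layer-selectivity checks of a preset study
#'
#' Evaluates the expected qualitative signatures of the four treatment
#' presets on a study's group means: injection constricts the reticular
#' dermis only; topical application constricts with a surface-inward
#' gradient (PD > RD > HD); whole-skin constriction orders topical >
#' injection > the non-responding arms; and the 60-min depth-centroid
#' displacement is larger under topical application than under injection.
#'
#' @param study A `pam_study` over the four preset groups.
#' @return Named logical vector of checks.
#' @export
qualitative_pattern_checks <- function(study) {
  cs <- study$constriction_summary
  pick <- function(g, l) cs$mean_pct[cs$group == g & cs$layer == l]
  disp <- study$centroids |>
    dplyr::filter(.data$t_min == max(.data$t_min)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(d = mean(.data$displacement_um))
  dsp <- function(g) disp$d[disp$group == g]
  c(
    injection_rd_constricts = pick("injection", "RD") > 20,
    injection_spares_pd = abs(pick("injection", "PD")) < 10,
    injection_spares_hd = abs(pick("injection", "HD")) < 10,
    topical_gradient = pick("topical", "PD") > pick("topical", "RD") &&
      pick("topical", "RD") > pick("topical", "HD"),
    whole_topical_over_injection =
      pick("topical", "WHOLE") > pick("injection", "WHOLE"),
    whole_injection_over_controls =
      pick("injection", "WHOLE") > pick("control", "WHOLE") &&
      pick("injection", "WHOLE") > pick("nonsteroid", "WHOLE"),
    controls_flat = abs(pick("control", "WHOLE")) < 10 &&
      abs(pick("nonsteroid", "WHOLE")) < 10,
    centroid_contrast = dsp("topical") > dsp("injection")
  )
}

#' Histogram peak recovery against the phantom's band centres
#'
#' Renders one baseline volume per seed (noiseless and at the spec's
#' noise level), runs surface detection, flattening, and peak finding,
#' and reports the recovered peak depths against the realised band
#' centres of the generated vessels.
#'
#' @param spec A [phantom_spec()] (its `noise_sd` is used for the noisy
#'   arm).
#' @param seeds Integer seeds, one phantom per seed.
#' @param config A [pipeline_config()].
#' @return Tibble: `seed`, `noise`, `pd_error_um`, `hd_error_um`.
#' @export
evaluate_peak_recovery <- function(spec = small_phantom_spec(),
                                   seeds = 1:20,
                                   config = pipeline_config()) {
  lc <- config$layers
  rows <- lapply(seeds, function(seed) {
    dplyr::bind_rows(lapply(c(FALSE, TRUE), function(noisy) {
      sp <- spec
      sp$seed <- as.integer(seed)
      if (!noisy) sp$noise_sd <- 0
      surf <- generate_surface(sp, seed = seed)
      vessels <- place_vessels(sp, seed = seed + 1L)
      vol <- render_volume(vessels, surf, sp, noise = noisy,
                           noise_seed = seed + 2L)
      flat <- flatten(vol, detect_surface(
        vol, frac = config$surface$frac,
        median_window = config$surface$median_window))
      h <- depth_histogram(flat, smooth_window_um = lc$smooth_window_um)
      pk <- find_layer_peaks(h, min_separation_um = lc$min_separation_um,
                             min_depth_um = lc$min_depth_um)
      truth <- phantom_truth(sp, vessels)
      tibble::tibble(seed = seed, noise = noisy,
                     pd_error_um = pk$depth_um[1] - truth$pd_depth_um,
                     hd_error_um = pk$depth_um[2] - truth$hd_depth_um)
    }))
  })
  dplyr::bind_rows(rows)
}
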