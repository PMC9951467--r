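#' Analytic ground truth of a phantom subject
#'
#' Bundles the baseline vessel set, its constriction schedules, and the
#' generating spec so that layer-wise projected vascular area fractions can
#' be evaluated at any timepoint from pure tube geometry, without rendering.
#'
#' @param spec The generating [phantom_spec()].
#' @param vessels Baseline vessel tibble.
#' @param schedules Named list of per-layer schedules.
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(spec, vessels, schedules = list()) {
  pd <- vessels$layer == "PD"
  hd <- vessels$layer == "HD"
  structure(list(
    spec = spec, vessels = vessels, schedules = schedules,
    pd_depth_um = if (any(pd)) {
      mean(vapply(vessels$centerline[pd], function(m) mean(m[, 3]), 0))
    } else spec$pd_depth_um,
    hd_depth_um = if (any(hd)) {
      mean(vapply(vessels$centerline[hd], function(m) mean(m[, 3]), 0))
    } else spec$hd_depth_um
  ), class = "phantom_truth")
}

#' Projected vascular area fraction of a vessel set
#'
#' Projects tube footprints onto the lateral plane and reports the covered
#' area fraction. `method = "grid"` (default) rasterises the union of
#' footprints on a supersampled lateral grid, so overlapping vessels are
#' not double counted; `method = "rect"` is the closed form
#' `sum(2 * r * L_lateral + pi * r^2) / area` which ignores overlap and is
#' exactly linear in the radius for a lone near-horizontal tube.
#'
#' @param vessels Vessel tibble.
#' @param field_um Lateral field size `c(X, Y)` in micrometres.
#' @param method `"grid"` or `"rect"`.
#' @param cell_um Cell size of the rasterisation grid (grid method).
#' @return Fraction in `[0, 1]`.
#' @export
projected_area_fraction <- function(vessels, field_um,
                                    method = c("grid", "rect"),
                                    cell_um = c(2.5, 2.5)) {
  method <- match.arg(method)
  area <- prod(field_um)
  if (nrow(vessels) == 0) return(0)
  if (method == "rect") {
    covered <- sum(vapply(seq_len(nrow(vessels)), function(i) {
      cl <- vessels$centerline[[i]]
      r <- vessels$radius_um[i]
      seg <- diff(cl[, 1:2, drop = FALSE])
      llen <- sum(sqrt(rowSums(seg^2)))
      2 * r * llen + pi * r^2
    }, 0))
    return(min(covered / area, 1))
  }
  ncx <- max(2L, ceiling(field_um[1] / cell_um[1]))
  ncy <- max(2L, ceiling(field_um[2] / cell_um[2]))
  mask <- cpp_project_tubes_mask(
    ncx, ncy, field_um[1] / ncx, field_um[2] / ncy,
    lapply(vessels$centerline, function(m) m[, 1:2, drop = FALSE]),
    as.numeric(vessels$radius_um))
  sum(mask) / (as.numeric(ncx) * ncy)
}

#' Oracle layer density of a phantom at a timepoint
#'
#' Evaluates the projected vascular area fraction of one layer's vessels
#' (or of the whole set) at time `t_min`, applying the truth's constriction
#' schedules analytically. This is the geometric oracle against which the
#' measured pipeline densities are validated.
#'
#' @param truth A [phantom_truth()].
#' @param layer `"PD"`, `"RD"`, `"HD"`, or `"WHOLE"`.
#' @param t_min Time in minutes.
#' @param method Passed to [projected_area_fraction()].
#' @return Fraction in `[0, 1]`.
#' @export
ground_truth_layer_density <- function(truth, layer, t_min = 0,
                                       method = c("grid", "rect")) {
  if (!layer %in% LAYER_SCOPES) {
    pam_abort(paste0("unknown layer tag: ", layer), "unknown_layer")
  }
  spec <- truth$spec
  vt <- apply_constriction(truth$vessels, truth$schedules, t_min)
  if (layer != "WHOLE") vt <- vt[vt$layer == layer, , drop = FALSE]
  field <- c((spec$nx - 1) * spec$spacing_um[1],
             (spec$ny - 1) * spec$spacing_um[2])
  cell <- pmin(spec$spacing_um[1:2] / 2, 2.5)
  projected_area_fraction(vt, field, method = match.arg(method),
                          cell_um = cell)
}

#' Oracle density trace and constriction for every layer scope
#'
#' @param truth A [phantom_truth()].
#' @param timepoints_min Timepoints to evaluate (defaults to the spec's).
#' @return Tibble with `layer`, `t_min`, `truth_frac`, and `truth_relative`
#'   (normalised to t = 0).
#' @export
truth_density_trace <- function(truth, timepoints_min = NULL) {
  tp <- timepoints_min %||% truth$spec$timepoints_min
  grid <- tidyr::expand_grid(layer = LAYER_SCOPES, t_min = tp)
  grid$truth_frac <- purrr::map2_dbl(grid$layer, grid$t_min, function(l, t) {
    ground_truth_layer_density(truth, l, t)
  })
  grid |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(truth_relative = {
      base <- .data$truth_frac[.data$t_min == 0]
      if (base > 0) .data$truth_frac / base else NA_real_
    }) |>
    dplyr::ungroup()
}
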