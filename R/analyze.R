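#' Analysis pipeline configuration
#'
#' Central knobs of the surface, layers, and quantify stages with the
#' package defaults. Any entry can be overridden by name.
#'
#' @param surface List: `frac` (A-line threshold fraction), `median_window`
#'   (median filter side), `noise_floor` (absolute; `NULL` = 0.2 x max),
#'   `outlier_mad` (deep-detection rejection).
#' @param layers List: `smooth_window_um` (histogram smoothing),
#'   `min_separation_um` (peak separation), `min_depth_um` (peak search
#'   start), `epidermis_um` (avascular zone excluded from the slabs),
#'   `boundary_rule` (`"valleys"` or `"peaks"`), `fix_to_t0`
#'   (segment once at t = 0 and reuse for the series).
#' @param quantify List: `n_bins` (Otsu), `centroid_min_depth_um`,
#'   `centroid_weighted`.
#' @return A `pam_config` list.
#' @export
pipeline_config <- function(surface = list(), layers = list(),
                            quantify = list()) {
  def <- list(
    surface = list(frac = 0.5, median_window = 11L, noise_floor = NULL,
                   outlier_mad = 3.5),
    layers = list(smooth_window_um = 30, min_separation_um = 100,
                  min_depth_um = 30, epidermis_um = 30,
                  boundary_rule = "valleys", fix_to_t0 = TRUE),
    quantify = list(n_bins = 256L, centroid_min_depth_um = 30,
                    centroid_weighted = FALSE)
  )
  def$surface[names(surface)] <- surface
  def$layers[names(layers)] <- layers
  def$quantify[names(quantify)] <- quantify
  structure(def, class = "pam_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pam_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(surface = raw$surface %||% list(),
                  layers = raw$layers %||% list(),
                  quantify = raw$quantify %||% list())
}

#' @rdname read_pipeline_config
#' @param config A `pam_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Analyse one subject's timepoint series
#'
#' Runs the full per-subject pipeline: detect the surface of every volume
#' and flatten it; segment the skin layers from the depth histogram of the
#' t = 0 volume (reused for the whole series by default, since the
#' constriction itself shifts the histogram); project layer-wise MAPs;
#' binarise each layer series with the averaged-Otsu threshold; and
#' compute density traces plus the depth centroid trace.
#'
#' @param volumes List of [pam_volume()]s of one subject (any order; they
#'   are sorted by `t_min`, which must start at 0).
#' @param config A [pipeline_config()].
#' @return List with `traces` (tibble over layer scopes and timepoints),
#'   `centroids` (tibble with `centroid_um` and `displacement_um`),
#'   `boundaries`, `histogram`, and `voxel_threshold`.
#' @export
analyze_subject <- function(volumes, config = pipeline_config()) {
  ord <- order(vapply(volumes, function(v) v$t_min, numeric(1)))
  volumes <- volumes[ord]
  t_min <- vapply(volumes, function(v) v$t_min, numeric(1))
  if (t_min[1] != 0) pam_abort("series must include t = 0", "invalid_series")
  sc <- config$surface
  lc <- config$layers
  qc <- config$quantify

  # timepoints are processed one at a time so that only a single flattened
  # volume is ever held alongside the input series
  hist0 <- NULL
  bounds0 <- NULL
  maps <- lapply(LAYER_SCOPES, function(s) vector("list", length(volumes)))
  names(maps) <- LAYER_SCOPES
  cent <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    s <- detect_surface(v, frac = sc$frac, noise_floor = sc$noise_floor,
                        median_window = sc$median_window,
                        outlier_mad = sc$outlier_mad)
    flat <- flatten(v, s)
    if (i == 1 || !isTRUE(lc$fix_to_t0)) {
      h <- depth_histogram(flat, smooth_window_um = lc$smooth_window_um,
                           n_bins = qc$n_bins)
      b <- segment_layers(h, rule = lc$boundary_rule,
                          epidermis_um = lc$epidermis_um,
                          min_separation_um = lc$min_separation_um,
                          min_depth_um = lc$min_depth_um)
      if (i == 1) {
        hist0 <- h
        bounds0 <- b
      }
    } else {
      b <- bounds0
    }
    for (scope in LAYERS) maps[[scope]][[i]] <- layer_map(flat, b, scope)
    maps$WHOLE[[i]] <- pam_map(
      pmax(maps$PD[[i]]$values, maps$RD[[i]]$values, maps$HD[[i]]$values),
      layer = "WHOLE", t_min = flat$t_min,
      subject_id = flat$subject_id, group = flat$group)
    cent[i] <- centroid_depth(flat, threshold = hist0$threshold,
                              min_depth_um = qc$centroid_min_depth_um,
                              weighted = qc$centroid_weighted)
    rm(flat)
  }

  sid <- volumes[[1]]$subject_id
  grp <- volumes[[1]]$group
  traces <- dplyr::bind_rows(lapply(LAYER_SCOPES, function(scope) {
    thr <- series_threshold(maps[[scope]], n_bins = qc$n_bins)
    dens <- vapply(maps[[scope]], vascular_density, numeric(1),
                   threshold = thr)
    relative_trace(dens, t_min, subject_id = sid, group = grp,
                   layer = scope, threshold = thr)
  }))
  centroids <- tibble::tibble(
    subject_id = sid, group = grp, t_min = t_min, centroid_um = cent,
    displacement_um = cent - cent[1])

  list(traces = traces, centroids = centroids, boundaries = bounds0,
       histogram = hist0, voxel_threshold = hist0$threshold)
}
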