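#' A photoacoustic amplitude volume
#'
#' Thin container around a 3-D non-negative amplitude array indexed
#' `(x, y, z)` with `z = 1` the shallowest slice, plus voxel spacing and
#' acquisition metadata.
#'
#' @param amplitude 3-D numeric array, all values `>= 0`.
#' @param spacing_um Voxel spacing `c(dx, dy, dz)` in micrometres.
#' @param t_min Acquisition time in minutes.
#' @param subject_id,group Provenance labels.
#' @param flattened Logical: is depth measured below the detected surface?
#' @return Object of class `pam_volume`.
#' @export
pam_volume <- function(amplitude, spacing_um, t_min = 0,
                       subject_id = NA_character_, group = NA_character_,
                       flattened = FALSE) {
  if (length(dim(amplitude)) != 3 || any(dim(amplitude) < 1)) {
    pam_abort("amplitude must be a non-empty 3-D array", "invalid_volume")
  }
  if (any(amplitude < 0)) {
    pam_abort("amplitude values must be >= 0", "invalid_volume")
  }
  if (length(spacing_um) != 3 || any(spacing_um <= 0)) {
    pam_abort("spacing_um must be three positive values", "invalid_volume")
  }
  structure(list(amplitude = amplitude, spacing_um = as.numeric(spacing_um),
                 t_min = t_min, subject_id = subject_id, group = group,
                 flattened = flattened),
            class = "pam_volume")
}

#' @export
print.pam_volume <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<pam_volume> %d x %d x %d voxels @ (%g, %g, %g) um, t = %g min%s\n",
    d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
    x$t_min, if (isTRUE(x$flattened)) " (flattened)" else ""))
  if (!is.na(x$subject_id)) {
    cat(sprintf("  subject %s, group %s\n", x$subject_id, x$group))
  }
  invisible(x)
}

#' A lateral maximum-amplitude projection (MAP) image
#'
#' @param values 2-D non-negative matrix in the lateral `(x, y)` plane.
#' @param layer Layer scope: `"PD"`, `"RD"`, `"HD"`, or `"WHOLE"`.
#' @param t_min Acquisition time.
#' @param subject_id,group Provenance labels.
#' @return Object of class `pam_map`.
#' @export
pam_map <- function(values, layer = "WHOLE", t_min = 0,
                    subject_id = NA_character_, group = NA_character_) {
  if (!is.matrix(values) || any(values < 0)) {
    pam_abort("MAP values must be a non-negative matrix", "invalid_map")
  }
  if (!layer %in% LAYER_SCOPES) {
    pam_abort(paste0("unknown layer tag: ", layer), "unknown_layer")
  }
  structure(list(values = values, layer = layer, t_min = t_min,
                 subject_id = subject_id, group = group),
            class = "pam_map")
}

#' @export
print.pam_map <- function(x, ...) {
  cat(sprintf("<pam_map> %s layer, %d x %d px, t = %g min\n",
              x$layer, nrow(x$values), ncol(x$values), x$t_min))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Page `k` of the TIFF is depth slice `z = k`. Amplitudes are stored as
#' 16-bit fractions of the recorded maximum; the exact scale and all
#' metadata live in a `<path>.json` sidecar so the round trip is lossless
#' up to the declared 16-bit quantisation.
#'
#' @param volume A [pam_volume()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  amp <- volume$amplitude
  amp_max <- max(amp, 1e-12)
  pages <- lapply(seq_len(dim(amp)[3]), function(k) amp[, , k] / amp_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(format = "pamvasc-volume", version = 1L,
               spacing_um = volume$spacing_um, t_min = volume$t_min,
               subject_id = volume$subject_id, group = volume$group,
               flattened = isTRUE(volume$flattened),
               amp_max = amp_max, bits = 16L,
               dim = dim(amp))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path Path to the multi-page TIFF; its `<path>.json` sidecar must
#'   exist and carry the voxel spacing — a missing sidecar or missing
#'   `spacing_um` key is an error, never a silent default.
#' @return A [pam_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    pam_abort(paste0("volume file not found: ", path), "io")
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    pam_abort(paste0("metadata sidecar not found: ", sc,
                     " (required key: spacing_um)"), "missing_metadata")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("spacing_um", "amp_max")) {
    if (is.null(meta[[key]])) {
      pam_abort(paste0("metadata sidecar lacks required key: ", key),
                "missing_metadata")
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  amp <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), nz))
  for (k in seq_len(nz)) amp[, , k] <- pages[[k]]
  amp <- amp * meta$amp_max
  pam_volume(amp, spacing_um = meta$spacing_um,
             t_min = meta$t_min %||% 0,
             subject_id = meta$subject_id %||% NA_character_,
             group = meta$group %||% NA_character_,
             flattened = isTRUE(meta$flattened))
}

#' Export a MAP image as a display PNG with recorded scaling
#'
#' Writes an 8-bit grayscale PNG scaled linearly over a fixed `(min, max)`
#' range recorded in a JSON sidecar, so the original amplitude range is
#' always recoverable. Quantification never uses these display exports;
#' they exist for figures only.
#'
#' @param map A [pam_map()].
#' @param path Output `.png` path.
#' @param range Scaling range; defaults to the image's own `(min, max)`.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path, range = NULL) {
  v <- map$values
  rg <- range %||% base::range(v)
  if (diff(rg) <= 0) rg[2] <- rg[1] + 1
  scaled <- pmin(pmax((v - rg[1]) / (rg[2] - rg[1]), 0), 1)
  # transpose so PNG rows correspond to y
  png::writePNG(t(scaled), path)
  jsonlite::write_json(
    list(format = "pamvasc-map-display", scale_min = rg[1],
         scale_max = rg[2], layer = map$layer, t_min = map$t_min,
         subject_id = map$subject_id, group = map$group, bits = 8L),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export one PNG per timepoint of a MAP series
#'
#' Files are named `<prefix>_<layer>_t<mmm>.png` with the timepoint in
#' minutes zero-padded, all scaled over the shared series range.
#'
#' @param maps List of [pam_map()]s from one subject/layer series.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
export_map_series <- function(maps, dir, prefix = "map") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rg <- range(unlist(lapply(maps, function(m) range(m$values))))
  paths <- vapply(maps, function(m) {
    p <- file.path(dir, sprintf("%s_%s_t%03d.png", prefix, m$layer,
                                as.integer(round(m$t_min))))
    write_map_png(m, p, range = rg)
    p
  }, character(1))
  invisible(paths)
}
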