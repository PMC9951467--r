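#' Generate a phantom study on disk (or in memory)
#'
#' Simulates every group x subject acquisition series. With `out_dir`,
#' volumes are written as multi-page TIFFs with JSON sidecars plus a
#' `study.json` manifest and a per-subject ground-truth JSON, and only
#' file paths are kept in memory; without it, the simulated subject
#' bundles are returned directly (sensible for small specs only).
#'
#' @param spec A [phantom_spec()].
#' @param groups Named list of per-layer schedule lists.
#' @param n_subjects Subjects per group.
#' @param seed Master seed; per-subject seeds derive deterministically.
#' @param out_dir Output directory, or `NULL` for in-memory.
#' @return With `out_dir`: the study manifest (invisibly); otherwise a
#'   named list of subject bundles from [simulate_subject()].
#' @export
generate_study <- function(spec = phantom_spec(), groups = steroid_presets(),
                           n_subjects = 6L, seed = 1L, out_dir = NULL) {
  if (anyDuplicated(names(groups)) || is.null(names(groups)) ||
      any(names(groups) == "")) {
    pam_abort("groups must have unique non-empty names", "invalid_groups")
  }
  if (n_subjects < 1) pam_abort("n_subjects must be >= 1", "invalid_groups")
  in_memory <- is.null(out_dir)
  if (!in_memory) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  manifest_subjects <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    for (si in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", gname, si)
      sseed <- subject_seed(seed, gi, si)
      sub <- simulate_subject(spec, schedules = groups[[gi]],
                              subject_id = sid, group = gname, seed = sseed)
      if (in_memory) {
        subjects[[sid]] <- sub
      } else {
        files <- vapply(sub$volumes, function(v) {
          f <- file.path(out_dir, sprintf("%s_t%03d.tif", sid,
                                          as.integer(round(v$t_min))))
          write_volume(v, f)
          basename(f)
        }, character(1))
        truth_file <- file.path(out_dir, paste0(sid, "_truth.json"))
        jsonlite::write_json(serialize_truth(sub$truth), truth_file,
                             auto_unbox = TRUE, digits = NA)
        manifest_subjects[[sid]] <- list(
          subject_id = sid, group = gname, seed = sseed,
          t_min = spec$timepoints_min, files = files,
          truth = basename(truth_file))
      }
      rm(sub)
    }
  }
  if (in_memory) return(subjects)
  manifest <- list(format = "pamvasc-study", version = 1L, seed = seed,
                   groups = names(groups), n_subjects = n_subjects,
                   timepoints_min = spec$timepoints_min,
                   subjects = unname(manifest_subjects))
  jsonlite::write_json(manifest, file.path(out_dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

serialize_truth <- function(truth) {
  list(
    pd_depth_um = truth$pd_depth_um, hd_depth_um = truth$hd_depth_um,
    schedules = lapply(truth$schedules, unclass),
    vessels = lapply(seq_len(nrow(truth$vessels)), function(i) {
      list(layer = truth$vessels$layer[i],
           radius_um = truth$vessels$radius_um[i],
           intensity = truth$vessels$intensity[i],
           centerline = truth$vessels$centerline[[i]])
    }))
}

#' Analyse a phantom study stored on disk
#'
#' Reads the `study.json` manifest written by [generate_study()], loads
#' each subject's volume series, and runs [analyze_subject()] on it.
#' Subjects with missing or unreadable volumes are reported in `issues`
#' and excluded — never silently dropped — and the group n in the manifest
#' reflects the subjects actually analysed.
#'
#' @param dir Study directory.
#' @param config A [pipeline_config()].
#' @return A `pam_study` (without the geometric oracle).
#' @export
analyze_study <- function(dir, config = pipeline_config()) {
  mf_path <- file.path(dir, "study.json")
  if (!file.exists(mf_path)) {
    pam_abort(paste0("study manifest not found: ", mf_path), "io")
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  traces <- list()
  centroids <- list()
  bound_rows <- list()
  issues <- list()
  for (subj in mf$subjects) {
    sid <- subj$subject_id
    paths <- file.path(dir, unlist(subj$files))
    missing <- !file.exists(paths)
    if (any(missing)) {
      issues[[sid]] <- paste0("missing volume file(s): ",
                              paste(basename(paths[missing]), collapse = ", "))
      next
    }
    res <- tryCatch({
      volumes <- lapply(paths, read_volume)
      analyze_subject(volumes, config = config)
    }, pamvasc_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      issues[[sid]] <- conditionMessage(res)
      next
    }
    traces[[sid]] <- res$traces
    centroids[[sid]] <- res$centroids
    b <- res$boundaries
    bound_rows[[sid]] <- tibble::tibble(
      subject_id = sid, group = subj$group,
      d_pd_um = (b$d_pd - 1) * b$dz, d_hd_um = (b$d_hd - 1) * b$dz,
      z_pd_rd_um = (b$z_pd_rd - 1) * b$dz,
      z_rd_hd_um = (b$z_rd_hd - 1) * b$dz, rule = b$rule)
  }
  if (!length(traces)) pam_abort("no subject could be analysed", "study_failed")
  traces <- dplyr::bind_rows(traces)
  constriction <- trace_constriction(traces)
  structure(list(
    traces = traces, constriction = constriction,
    centroids = dplyr::bind_rows(centroids),
    boundaries = dplyr::bind_rows(bound_rows),
    summaries = group_summary(traces),
    constriction_summary = constriction_summary(constriction),
    truth = NULL, issues = issues,
    manifest = list(seed = mf$seed, n_subjects = mf$n_subjects,
                    groups = unlist(mf$groups),
                    timepoints_min = unlist(mf$timepoints_min),
                    config = unclass(config),
                    n_analyzed = dplyr::n_distinct(traces$subject_id),
                    n_failed = length(issues),
                    package = as.character(utils::packageVersion("pamvasc")))
  ), class = "pam_study")
}
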