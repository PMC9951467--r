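#' Simulate and analyse a full multi-group phantom study
#'
#' For every group x subject, simulates a 7-timepoint acquisition series
#' from the phantom spec with the group's constriction schedules and runs
#' the complete analysis pipeline on it, streaming subjects one at a time
#' so only a single series is in memory. Each subject's analytic ground
#' truth (projected-area oracle) is evaluated alongside.
#'
#' @param spec A [phantom_spec()] (shared by all subjects; each subject
#'   gets its own seed derived from `seed`).
#' @param groups Named list of group definitions — per-layer schedule
#'   lists as produced by [steroid_presets()].
#' @param n_subjects Subjects per group.
#' @param seed Master seed.
#' @param config A [pipeline_config()].
#' @param with_truth Evaluate the geometric oracle per subject.
#' @param progress Print per-subject progress.
#' @return A `pam_study` object bundling `traces`, `constriction`,
#'   `centroids`, `summaries`, `truth`, `boundaries`, `issues`, and a
#'   reproducibility `manifest`.
#' @export
run_study <- function(spec = phantom_spec(), groups = steroid_presets(),
                      n_subjects = 6L, seed = 1L,
                      config = pipeline_config(), with_truth = TRUE,
                      progress = FALSE) {
  if (anyDuplicated(names(groups)) || is.null(names(groups)) ||
      any(names(groups) == "")) {
    pam_abort("groups must have unique non-empty names", "invalid_groups")
  }
  if (n_subjects < 1) pam_abort("n_subjects must be >= 1", "invalid_groups")

  traces <- list()
  centroids <- list()
  truth_rows <- list()
  bound_rows <- list()
  issues <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    for (si in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", gname, si)
      sseed <- subject_seed(seed, gi, si)
      sub <- simulate_subject(spec, schedules = groups[[gi]],
                              subject_id = sid, group = gname, seed = sseed)
      res <- tryCatch(analyze_subject(sub$volumes, config = config),
                      pamvasc_error = function(e) e)
      if (inherits(res, "error")) {
        issues[[sid]] <- conditionMessage(res)
        if (progress) message(sid, ": FAILED (", conditionMessage(res), ")")
        next
      }
      traces[[sid]] <- res$traces
      centroids[[sid]] <- res$centroids
      b <- res$boundaries
      bound_rows[[sid]] <- tibble::tibble(
        subject_id = sid, group = gname,
        d_pd_um = (b$d_pd - 1) * b$dz, d_hd_um = (b$d_hd - 1) * b$dz,
        z_pd_rd_um = (b$z_pd_rd - 1) * b$dz,
        z_rd_hd_um = (b$z_rd_hd - 1) * b$dz, rule = b$rule)
      if (with_truth) {
        tt <- truth_density_trace(sub$truth)
        tt$subject_id <- sid
        tt$group <- gname
        truth_rows[[sid]] <- tt
      }
      if (progress) message(sid, ": ok")
      rm(sub)
    }
  }
  if (!length(traces)) {
    pam_abort("every subject failed analysis", "study_failed")
  }
  traces <- dplyr::bind_rows(traces)
  constriction <- trace_constriction(traces)
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else NULL
  structure(list(
    traces = traces,
    constriction = constriction,
    centroids = dplyr::bind_rows(centroids),
    boundaries = dplyr::bind_rows(bound_rows),
    summaries = group_summary(traces),
    constriction_summary = constriction_summary(constriction),
    truth = truth,
    issues = issues,
    manifest = list(seed = seed, n_subjects = n_subjects,
                    groups = names(groups),
                    timepoints_min = spec$timepoints_min,
                    grid = c(spec$nx, spec$ny, spec$nz),
                    spacing_um = spec$spacing_um,
                    config = unclass(config),
                    n_analyzed = dplyr::n_distinct(traces$subject_id),
                    n_failed = length(issues),
                    package = as.character(utils::packageVersion("pamvasc")))
  ), class = "pam_study")
}

#' @export
print.pam_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pam_study> %d group(s) x %d subject(s), %d timepoints\n",
              length(m$groups), m$n_subjects, length(m$timepoints_min)))
  cat(sprintf("  analysed %d subject(s), %d failed\n", m$n_analyzed,
              m$n_failed))
  print(x$constriction_summary, n = Inf)
  invisible(x)
}

#' Group-level summary of relative density traces
#'
#' Pointwise mean and standard error of the mean (sample SD over sqrt(n))
#' of the relative vascular density across the subjects of each group and
#' layer.
#'
#' @param traces Trace tibble (from [analyze_subject()] or a study).
#' @return Tibble: `group`, `layer`, `t_min`, `mean_relative`,
#'   `sem_relative`, `n`.
#' @export
group_summary <- function(traces) {
  traces |>
    dplyr::group_by(.data$group, .data$layer, .data$t_min) |>
    dplyr::summarise(
      mean_relative = mean(.data$relative),
      sem_relative = if (dplyr::n() >= 2) {
        sd(.data$relative) / sqrt(dplyr::n())
      } else NA_real_,
      n = dplyr::n(), .groups = "drop")
}

#' Group-level constriction summary (final timepoint)
#'
#' @param constriction Per-subject constriction tibble from
#'   [trace_constriction()].
#' @return Tibble: `group`, `layer`, `mean_pct`, `sem_pct`, `n`.
#' @export
constriction_summary <- function(constriction) {
  constriction |>
    dplyr::group_by(.data$group, .data$layer) |>
    dplyr::summarise(
      mean_pct = mean(.data$constriction_pct),
      sem_pct = if (dplyr::n() >= 2) {
        sd(.data$constriction_pct) / sqrt(dplyr::n())
      } else NA_real_,
      n = dplyr::n(), .groups = "drop")
}

#' Two-tailed paired t-test
#'
#' Pairs `a` and `b` by index, tests the mean difference against zero
#' (`t = mean(d) / (sd(d) / sqrt(n))`, n - 1 degrees of freedom), and
#' labels the significance band used in the study figures
#' (`p < 0.005` / `p < 0.05` / ns).
#'
#' @param a,b Numeric vectors of equal length `>= 2`, matched by index.
#' @param label Optional comparison label.
#' @return Object of class `pam_ttest` with `t`, `p`, `df`, `n`, `band`.
#' @export
paired_ttest <- function(a, b, label = NULL) {
  if (length(a) != length(b) || length(a) < 2) {
    pam_abort("paired test needs two equal-length vectors of n >= 2",
              "invalid_test")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    pam_abort("paired test requires finite values", "invalid_test")
  }
  d <- a - b
  if (sd(d) == 0) {
    pam_abort("degenerate test: differences have zero variance",
              "degenerate_test")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  p <- unname(tt$p.value)
  structure(list(
    t = unname(tt$statistic), p = p, df = unname(tt$parameter),
    n = length(a), mean_diff = unname(tt$estimate),
    band = if (p < 0.005) "***" else if (p < 0.05) "**" else "ns",
    label = label %||% "paired comparison"),
    class = "pam_ttest")
}

#' @export
print.pam_ttest <- function(x, ...) {
  cat(sprintf("<pam_ttest> %s: t(%d) = %.4f, p = %.4g [%s]\n",
              x$label, x$df, x$t, x$p, x$band))
  invisible(x)
}

#' @method tidy pam_ttest
#' @export
tidy.pam_ttest <- function(x, ...) {
  tibble::tibble(label = x$label, estimate = x$mean_diff, statistic = x$t,
                 p.value = x$p, parameter = x$df, n = x$n, band = x$band)
}

#' Default comparison list for the constriction statistics
#'
#' Between-group contrasts of each treated arm against control within each
#' layer, plus the within-group layer contrasts highlighted by the study
#' design (PD vs RD under injection, PD vs HD under topical application).
#'
#' @return List of comparison descriptors consumed by
#'   [compare_constriction()].
#' @export
default_comparisons <- function() {
  c(
    lapply(LAYERS, function(l) list(type = "between", layer = l,
                                    a = "injection", b = "control")),
    lapply(LAYERS, function(l) list(type = "between", layer = l,
                                    a = "topical", b = "control")),
    list(list(type = "within", group = "injection", a = "PD", b = "RD"),
         list(type = "within", group = "topical", a = "PD", b = "HD"))
  )
}

#' Significance tests on per-subject constrictions
#'
#' Runs two-tailed paired t-tests over a configurable comparison list:
#' `"between"` comparisons contrast one layer's constriction between two
#' groups (subjects paired by index, following the study's analysis
#' convention), `"within"` comparisons contrast two layers within one
#' group (naturally paired by subject). Comparisons whose groups are
#' absent are skipped.
#'
#' @param study A `pam_study`, or a per-subject constriction tibble.
#' @param comparisons List of descriptors, see [default_comparisons()].
#' @param method `"paired"` (the study convention, also between groups of
#'   different subjects) or `"welch"` (unpaired unequal-variance, arguably
#'   more appropriate between independent groups).
#' @param p_adjust `"none"` (raw two-tailed p with fixed bands) or
#'   `"bonferroni"`.
#' @return Tibble of tidy test results.
#' @export
compare_constriction <- function(study, comparisons = default_comparisons(),
                                 method = c("paired", "welch"),
                                 p_adjust = c("none", "bonferroni")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  con <- if (inherits(study, "pam_study")) study$constriction else study
  pull_vec <- function(grp, layer) {
    x <- con[con$group == grp & con$layer == layer, ]
    x <- x[order(x$subject_id), ]
    x$constriction_pct
  }
  rows <- lapply(comparisons, function(cmp) {
    res <- tryCatch({
      if (cmp$type == "between") {
        a <- pull_vec(cmp$a, cmp$layer)
        b <- pull_vec(cmp$b, cmp$layer)
        lab <- sprintf("%s: %s vs %s", cmp$layer, cmp$a, cmp$b)
      } else {
        a <- pull_vec(cmp$group, cmp$a)
        b <- pull_vec(cmp$group, cmp$b)
        lab <- sprintf("%s: %s vs %s", cmp$group, cmp$a, cmp$b)
      }
      if (!length(a) || !length(b) || length(a) != length(b)) return(NULL)
      if (method == "welch") {
        tt <- stats::t.test(a, b, paired = FALSE, var.equal = FALSE)
        tibble::tibble(label = lab, estimate = unname(diff(rev(tt$estimate))),
                       statistic = unname(tt$statistic),
                       p.value = unname(tt$p.value),
                       parameter = unname(tt$parameter), n = length(a),
                       band = NA_character_)
      } else {
        tidy(paired_ttest(a, b, label = lab))
      }
    }, pamvasc_error = function(e) NULL)
    res
  })
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) return(out)
  if (p_adjust == "bonferroni") {
    out$p.value <- stats::p.adjust(out$p.value, "bonferroni")
  }
  out$band <- ifelse(out$p.value < 0.005, "***",
                     ifelse(out$p.value < 0.05, "**", "ns"))
  out
}

#' Write a study's result tables to disk
#'
#' Emits `traces.csv`, `centroids.csv`, `summaries.csv`,
#' `constriction.csv`, `boundaries.csv`, `tests.csv`, and a
#' `manifest.json` into `dir`.
#'
#' @param study A `pam_study`.
#' @param dir Output directory (created if missing).
#' @param comparisons Passed to [compare_constriction()].
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir,
                                comparisons = default_comparisons()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(study$traces, "traces.csv")
  wr(study$centroids, "centroids.csv")
  wr(study$summaries, "summaries.csv")
  wr(study$constriction_summary, "constriction.csv")
  wr(study$boundaries, "boundaries.csv")
  tests <- compare_constriction(study, comparisons)
  if (nrow(tests)) wr(tests, "tests.csv")
  manifest <- study$manifest
  manifest$issues <- study$issues
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @method tidy pam_study
#' @export
tidy.pam_study <- function(x, ...) x$traces

#' @method glance pam_study
#' @export
glance.pam_study <- function(x, ...) {
  x$constriction_summary |>
    tidyr::pivot_wider(names_from = "layer",
                       values_from = c("mean_pct", "sem_pct"),
                       id_cols = "group") |>
    dplyr::mutate(n = x$manifest$n_subjects)
}
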