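test_that("group summaries report pointwise means and SEMs", {
  tr1 <- relative_trace(c(100, 80), c(0, 60), "s1", "g", "PD")
  tr2 <- relative_trace(c(200, 160), c(0, 60), "s2", "g", "PD")
  gs <- group_summary(dplyr::bind_rows(tr1, tr2))
  expect_equal(gs$sem_relative, c(0, 0)) # identical relative traces
  expect_equal(gs$mean_relative, c(1, 0.8))
  expect_equal(gs$n, c(2, 2))

  # final relative densities 0.4 and 0.6: constriction 50 +/- 10
  tra <- relative_trace(c(100, 40), c(0, 60), "s1", "g", "RD")
  trb <- relative_trace(c(100, 60), c(0, 60), "s2", "g", "RD")
  cs <- constriction_summary(trace_constriction(dplyr::bind_rows(tra, trb)))
  expect_equal(cs$mean_pct, 50)
  expect_equal(cs$sem_pct, 10) # sd({40, 60}) / sqrt(2)
})

test_that("paired t-test matches the textbook closed form", {
  a <- c(2, 4, 6)
  b <- c(1, 2, 3) # differences 1, 2, 3
  res <- paired_ttest(a, b)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(3))
  p_closed <- 2 * stats::pt(-abs(t_closed), df = 2)
  expect_equal(res$t, t_closed, tolerance = 1e-9)
  expect_equal(res$p, p_closed, tolerance = 1e-9)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$band, "ns")

  # symmetry: swapping the arguments negates t, preserves p
  swapped <- paired_ttest(b, a)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  expect_error(paired_ttest(a, a), class = "pamvasc_degenerate_test")
  expect_error(paired_ttest(1:3, 1:4), class = "pamvasc_invalid_test")
  expect_error(paired_ttest(c(1, NA, 3), 1:3),
               class = "pamvasc_invalid_test")

  tidy_res <- tidy(res)
  expect_s3_class(tidy_res, "tbl_df")
  expect_equal(tidy_res$statistic, res$t)
})

test_that("constriction comparisons pair subjects and label bands", {
  con <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                            group = c("injection", "control"),
                            layer = c("PD", "RD", "HD"))
  subj <- as.integer(sub("s", "", con$subject_id))
  # a strong RD effect under injection; elsewhere mean-zero wobble whose
  # paired differences cancel exactly
  con$constriction_pct <- ifelse(
    con$group == "injection" & con$layer == "RD",
    50 + subj, (-1)^subj * ifelse(con$group == "injection", 1, -1))
  res <- compare_constriction(con)
  expect_s3_class(res, "tbl_df")
  rd <- res[res$label == "RD: injection vs control", ]
  expect_equal(rd$band, "***") # p < 0.005 at this effect size
  expect_equal(rd$n, 6)
  pd <- res[res$label == "PD: injection vs control", ]
  expect_equal(pd$band, "ns")
  # within-group contrast present and paired by subject
  expect_true("injection: PD vs RD" %in% res$label)
})

test_that("an in-memory study run is deterministic and well-formed", {
  spec <- tiny_spec()
  groups <- list(injection = steroid_presets()$injection,
                 control = list())
  st <- run_study(spec, groups, n_subjects = 2, seed = 7)
  expect_s3_class(st, "pam_study")
  expect_equal(nrow(st$traces), 2 * 2 * 4 * 7) # groups x subjects x scopes x t
  expect_length(st$issues, 0)
  expect_true(all(st$traces$relative[st$traces$t_min == 0] == 1))

  st2 <- run_study(spec, groups, n_subjects = 2, seed = 7)
  expect_identical(st$traces, st2$traces) # rerun is bit-identical
  expect_identical(st$centroids, st2$centroids)

  # oracle is attached per subject and starts at 1
  expect_true(all(st$truth$truth_relative[st$truth$t_min == 0] == 1))

  # accessors
  expect_identical(tidy(st), st$traces)
  g <- glance(st)
  expect_true("mean_pct_RD" %in% names(g))
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
})

test_that("a disk study analyses end-to-end and flags missing volumes", {
  spec <- tiny_spec()
  groups <- list(control = list())
  dir <- withr::local_tempdir()
  generate_study(spec, groups, n_subjects = 2, seed = 9, out_dir = dir)
  expect_true(file.exists(file.path(dir, "study.json")))

  st <- analyze_study(dir)
  expect_equal(st$manifest$n_analyzed, 2)
  expect_length(st$issues, 0)

  # deleting one timepoint excludes (and reports) that subject only
  victim <- list.files(dir, pattern = "control_01_t040\\.tif$",
                       full.names = TRUE)
  file.remove(victim, paste0(victim, ".json"))
  st2 <- analyze_study(dir)
  expect_equal(st2$manifest$n_analyzed, 1)
  expect_match(st2$issues[["control_01"]], "t040")

  # written result tables are rerun-stable
  out1 <- withr::local_tempdir()
  write_study_results(st2, out1)
  expect_true(all(file.exists(file.path(out1,
    c("traces.csv", "summaries.csv", "manifest.json")))))
})

test_that("pipeline configuration round-trips through YAML", {
  cfg <- pipeline_config(layers = list(boundary_rule = "peaks",
                                       min_separation_um = 80),
                         surface = list(frac = 0.4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  back <- read_pipeline_config(path)
  expect_equal(back$layers$boundary_rule, "peaks")
  expect_equal(back$layers$min_separation_um, 80)
  expect_equal(back$surface$frac, 0.4)
  # untouched entries keep their defaults
  expect_equal(back$quantify$n_bins, pipeline_config()$quantify$n_bins)
})
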