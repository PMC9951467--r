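test_that("Otsu separates a two-level image and rejects a constant one", {
  v <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0)
  expect_lt(thr, 10)
  expect_gt(sum(v > thr), 0)
  expect_gt(sum(v <= thr), 0)
  expect_error(otsu_threshold(rep(3, 100)),
               class = "pamvasc_degenerate_image")
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  for (seed in 1:20) {
    img <- random_test_image(seed)
    expect_identical(otsu_threshold(img), otsu_oracle(img),
                     label = paste("seed", seed))
  }
  # the C++ binning fast path matches the R path on large inputs
  withr::with_seed(1, big <- runif(1.2e6))
  expect_equal(otsu_threshold(big), otsu_oracle(big))
})

test_that("series threshold averages per-map Otsu thresholds", {
  base <- matrix(c(rep(0, 60), rep(1, 40)), 10, 10)
  maps <- lapply(1:7, function(i) pam_map(base, layer = "PD"))
  expect_equal(series_threshold(maps), otsu_threshold(base))

  # maps with distinct levels: mean of the individual thresholds
  levels <- 1:4
  maps2 <- lapply(levels, function(v) base * v)
  expect_equal(series_threshold(maps2),
               mean(vapply(maps2, otsu_threshold, 0)))

  # scaling all maps scales the threshold and leaves the masks unchanged
  thr <- series_threshold(maps2)
  thr2 <- series_threshold(lapply(maps2, function(m) m * 2))
  expect_equal(thr2, 2 * thr)
  for (m in maps2) expect_identical(m > thr, (m * 2) > thr2)

  expect_error(series_threshold(maps[1]), class = "pamvasc_invalid_series")
  expect_error(series_threshold(list(base, matrix(0, 3, 3))),
               class = "pamvasc_invalid_series")
  expect_error(series_threshold(list(base, matrix(1, 10, 10))),
               regexp = "index 2", class = "pamvasc_degenerate_image")
})

test_that("vascular density counts strictly suprathreshold pixels", {
  expect_equal(vascular_density(matrix(0, 5, 5), 0.5), 0)
  m <- matrix(0, 5, 5)
  m[1:5] <- 2
  expect_equal(vascular_density(m, 1), 5)
  expect_equal(vascular_density(m, max(m)), 0) # strict inequality
  expect_error(vascular_density(m, Inf), class = "pamvasc_invalid_threshold")
})

test_that("relative traces normalise to t = 0 and report constriction", {
  tr <- relative_trace(c(200, 100), c(0, 60), subject_id = "a", layer = "RD")
  expect_equal(tr$relative, c(1, 0.5))
  expect_equal(trace_constriction(tr)$constriction_pct, 50)

  const <- relative_trace(rep(77, 7), seq(0, 60, 10))
  expect_true(all(const$relative == 1))
  expect_equal(trace_constriction(const)$constriction_pct, 0)

  expect_error(relative_trace(c(0, 10), c(0, 10)),
               class = "pamvasc_undefined_baseline")
  # relative at baseline is exactly 1 for arbitrary integer densities
  for (seed in 1:10) {
    d <- withr::with_seed(seed, sample(1:500, 7))
    expect_identical(relative_trace(d, seq(0, 60, 10))$relative[1], 1)
  }
})

test_that("centroid depth averages suprathreshold voxel depths", {
  amp <- array(0, c(4, 4, 6))
  amp[1:2, 1, 3] <- 1 # two voxels at depth index 3 -> 6 um at dz = 3
  amp[3:4, 1, 5] <- 1 # two voxels at depth index 5 -> 12 um
  flat <- pam_volume(amp, c(5, 10, 3), flattened = TRUE)
  expect_equal(centroid_depth(flat, threshold = 0.5), 9)

  # scaling per-depth counts equally leaves the centroid unchanged
  amp2 <- amp
  amp2[2, 1, 3] <- 0
  amp2[4, 1, 5] <- 0
  expect_equal(centroid_depth(pam_volume(amp2, c(5, 10, 3), flattened = TRUE),
                              threshold = 0.5), 9)

  # amplitude weighting shifts toward the brighter depth
  amp3 <- amp
  amp3[1:2, 1, 3] <- 3
  w <- centroid_depth(pam_volume(amp3, c(5, 10, 3), flattened = TRUE),
                      threshold = 0.5, weighted = TRUE)
  expect_lt(w, 9)

  expect_error(centroid_depth(flat, threshold = 10),
               class = "pamvasc_empty_mask")
  expect_equal(centroid_depth(flat, threshold = 0.5, min_depth_um = 10), 12)
})

test_that("measured constriction increases with the schedule depth", {
  spec <- small_phantom_spec()
  measured <- vapply(c(0.2, 0.4, 0.6), function(cm) {
    sub <- simulate_subject(
      spec, list(RD = constriction_schedule(cm, 20)), seed = 19,
      subject_id = sprintf("c%02.0f", cm * 100), group = "x")
    res <- analyze_subject(sub$volumes)
    con <- trace_constriction(res$traces)
    con$constriction_pct[con$layer == "RD"]
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})
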