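test_that("depth histogram counts suprathreshold voxels per depth", {
  zero <- pam_volume(array(0, c(5, 4, 10)), c(5, 10, 3), flattened = TRUE)
  h0 <- depth_histogram(zero, threshold = 0.5)
  expect_true(all(h0$counts == 0))

  # a bright band occupying depths 11..15 only
  amp <- array(0, c(5, 4, 20))
  amp[2:4, 2:3, 11:15] <- 1
  vol <- pam_volume(amp, c(5, 10, 3), flattened = TRUE)
  h <- depth_histogram(vol, threshold = 0.5, smooth_window = 1)
  expect_true(all(h$counts[11:15] > 0))
  expect_true(all(h$counts[-(11:15)] == 0))

  # doubling amplitudes and the threshold leaves counts unchanged
  vol2 <- pam_volume(amp * 2, c(5, 10, 3), flattened = TRUE)
  h2 <- depth_histogram(vol2, threshold = 1.0, smooth_window = 1)
  expect_identical(h$counts, h2$counts)
})

test_that("peak finding locates the two most prominent maxima", {
  h <- make_hist(c(0, 1, 5, 2, 1, 4, 1))
  pk <- find_layer_peaks(h, min_separation_um = 1)
  expect_equal(pk$d_pd, 3L) # value 5 (0-based index 2)
  expect_equal(pk$d_hd, 6L) # value 4 (0-based index 5)
  expect_equal(pk$depth_um, c(2, 5))

  # unimodal counts: segmentation error reporting one peak
  expect_error(find_layer_peaks(make_hist(c(0, 1, 4, 9, 4, 1, 0)),
                                min_separation_um = 1),
               regexp = "found 1", class = "pamvasc_segmentation")
  expect_error(find_layer_peaks(make_hist(rep(0, 10))),
               class = "pamvasc_segmentation")

  # min_separation suppresses a nearby shoulder in favour of the far peak
  counts <- c(0, 10, 6, 8, 0, 0, 0, 0, 0, 9, 0)
  close <- find_layer_peaks(make_hist(counts), min_separation_um = 3)
  expect_equal(c(close$d_pd, close$d_hd), c(2L, 10L))
})

test_that("slab segmentation applies the requested boundary rule", {
  nzc <- numeric(200)
  nzc[21] <- 100
  nzc[30:120] <- 5
  nzc[167] <- 120
  nzc[140:160] <- 8
  h <- make_hist(nzc)
  pk <- list(d_pd = 21L, d_hd = 167L)

  b_peaks <- segment_layers(h, pk, rule = "peaks")
  expect_equal(b_peaks$z_pd_rd, 21L)
  expect_equal(b_peaks$z_rd_hd, 167L)
  expect_equal(layer_slab(b_peaks, "PD"), c(1L, 21L))
  expect_equal(layer_slab(b_peaks, "RD"), c(22L, 166L))
  expect_equal(layer_slab(b_peaks, "HD"), c(167L, 200L))

  # valleys rule: boundaries at the least-count depths (plateau centre)
  b_val <- segment_layers(h, pk, rule = "valleys")
  expect_gt(b_val$z_pd_rd, 21L)
  expect_lt(b_val$z_rd_hd, 167L)
  expect_equal(unname(h$smoothed[b_val$z_pd_rd]), 0)

  # adjacent peaks leave no reticular slab
  expect_error(segment_layers(h, list(d_pd = 5L, d_hd = 6L)),
               class = "pamvasc_segmentation")
  # epidermis exclusion cannot swallow the papillary slab
  expect_error(segment_layers(h, pk, rule = "peaks", epidermis_um = 500),
               class = "pamvasc_segmentation")
})

test_that("phantom vessel centres fall in their segmented slabs", {
  spec <- tiny_spec()
  sub <- simulate_subject(spec, seed = 21)
  res <- analyze_subject(sub$volumes)
  b <- res$boundaries
  dz <- spec$spacing_um[3]
  pd_lim <- (b$z_pd_rd - 1) * dz
  hd_lim <- (b$z_rd_hd - 1) * dz
  v <- sub$vessels
  centre <- vapply(v$centerline, function(m) mean(m[, 3]), 0)
  slack <- 15 # surface-reference offset, um
  expect_true(all(centre[v$layer == "PD"] < pd_lim + slack))
  expect_true(all(centre[v$layer == "HD"] > hd_lim - slack))
})

test_that("layer maps tile the depth axis and conserve the WHOLE map", {
  withr::with_seed(5, amp <- array(runif(20 * 18 * 120), c(20, 18, 120)))
  flat <- pam_volume(amp, c(5, 10, 3), flattened = TRUE)
  h <- depth_histogram(flat, threshold = 0.5)
  b <- segment_layers(h, list(d_pd = 20L, d_hd = 90L), rule = "peaks")
  maps <- lapply(c("PD", "RD", "HD", "WHOLE"), function(l) layer_map(flat, b, l))
  names(maps) <- c("PD", "RD", "HD", "WHOLE")
  # conservation: pixelwise max of the three slabs equals the WHOLE map
  expect_equal(pmax(maps$PD$values, maps$RD$values, maps$HD$values),
               maps$WHOLE$values)
  for (l in c("PD", "RD", "HD")) {
    expect_true(all(maps$WHOLE$values >= maps[[l]]$values))
  }
  expect_error(layer_map(flat, b, "XX"), class = "pamvasc_unknown_layer")

  # a single bright voxel in the reticular slab appears only in the RD map
  amp2 <- array(0, c(10, 10, 120))
  amp2[4, 7, 50] <- 9
  flat2 <- pam_volume(amp2, c(5, 10, 3), flattened = TRUE)
  m <- lapply(c("PD", "RD", "HD"), function(l) layer_map(flat2, b, l))
  expect_equal(m[[2]]$values[4, 7], 9)
  expect_equal(m[[1]]$values[4, 7], 0)
  expect_equal(m[[3]]$values[4, 7], 0)
})

test_that("B-scan projection collapses the Y axis", {
  amp <- array(0, c(8, 6, 10))
  amp[3, 5, 7] <- 2
  vol <- pam_volume(amp, c(5, 10, 3))
  bs <- b_scan_map(vol)
  expect_equal(dim(bs), c(8, 10))
  expect_equal(bs[3, 7], 2)
  expect_equal(sum(bs > 0), 1)
  expect_true(all(b_scan_map(pam_volume(array(0, c(4, 4, 4)), c(1, 1, 1))) == 0))

  # the phantom's stratification shows as two deep bands of high amplitude
  spec <- tiny_spec(noise_sd = 0)
  sub <- simulate_subject(spec, seed = 2)
  flat <- flatten(sub$volumes[[1]], detect_surface(sub$volumes[[1]]))
  prof <- apply(b_scan_map(flat), 2, max)
  depth <- (seq_along(prof) - 1) * spec$spacing_um[3]
  expect_gt(max(prof[depth > 60 & depth < 150]), 0.5)  # papillary band
  expect_gt(max(prof[depth > 380 & depth < 520]), 0.5) # hypodermal band
  expect_lt(max(prof[depth > 560]), 0.3)               # below the anatomy
})
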