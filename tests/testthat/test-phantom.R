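test_that("constriction schedule follows the saturating-exponential form", {
  sch <- constriction_schedule(c_max = 0.5, tau_min = 20)
  expect_equal(constriction_factor(sch, 0), 1)
  # closed form evaluated independently
  expect_equal(constriction_factor(sch, 20), 1 - 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  # tau -> 0: factor reaches the asymptote 1 - c_max
  fast <- constriction_schedule(0.5, tau_min = 1e-6)
  expect_equal(constriction_factor(fast, 60), 0.5, tolerance = 1e-9)
  # monotone non-increasing for both forms
  tgrid <- seq(0, 120, by = 5)
  for (form in c("exponential", "linear")) {
    f <- constriction_factor(constriction_schedule(0.4, 25, form), tgrid)
    expect_true(all(diff(f) <= 1e-12))
    expect_equal(f[1], 1)
  }
  expect_error(constriction_factor(sch, -1), class = "pamvasc_invalid_time")
  expect_error(constriction_schedule(1.0), class = "pamvasc_invalid_schedule")
  expect_error(constriction_schedule(0.5, tau_min = 0),
               class = "pamvasc_invalid_schedule")
})

test_that("apply_constriction scales only the scheduled layer", {
  v <- place_vessels(tiny_spec(), seed = 7)
  sch <- list(RD = constriction_schedule(0.5, 20))
  v0 <- apply_constriction(v, sch, 0)
  expect_equal(v0$radius_um, v$radius_um) # identity at t = 0
  v60 <- apply_constriction(v, sch, 60)
  f <- constriction_factor(sch$RD, 60)
  is_rd <- v$layer == "RD"
  expect_equal(v60$radius_um[is_rd], v$radius_um[is_rd] * f)
  expect_equal(v60$radius_um[!is_rd], v$radius_um[!is_rd])
  expect_error(apply_constriction(v, sch, -5), class = "pamvasc_invalid_time")
  expect_error(apply_constriction(v, list(XX = sch$RD), 10),
               class = "pamvasc_unknown_layer")
})

test_that("vessel placement respects counts, tags, and geometry", {
  spec <- tiny_spec(n_pd = 2L, n_rd = 3L, n_hd_pairs = 1L)
  v <- place_vessels(spec, seed = 3)
  expect_equal(sum(v$layer == "PD"), 2)
  expect_equal(sum(v$layer == "RD"), 3)
  expect_equal(sum(v$layer == "HD"), 2) # one arteriole-venule pair
  expect_equal(sort(unique(v$layer)), sort(unique(c(v$layer)))) # single tag each

  # zero counts conserve exactly
  v0 <- place_vessels(tiny_spec(n_pd = 0L, n_rd = 0L, n_hd_pairs = 1L), seed = 1)
  expect_true(all(v0$layer == "HD"))
  expect_equal(nrow(v0), 2)

  # hypodermal vessels are larger than papillary ones (defaults, fixed seed)
  vd <- place_vessels(phantom_spec(), seed = 5)
  expect_gt(mean(vd$radius_um[vd$layer == "HD"]),
            mean(vd$radius_um[vd$layer == "PD"]))

  # reticular connectors are near-vertical: depth span exceeds lateral extent
  for (seed in 1:5) {
    vv <- place_vessels(tiny_spec(), seed = seed)
    rd <- vv[vv$layer == "RD", ]
    dz_span <- vapply(rd$centerline, function(m) diff(range(m[, 3])), 0)
    lat_ext <- vapply(rd$centerline, function(m) {
      max(diff(range(m[, 1])), diff(range(m[, 2])))
    }, 0)
    expect_gt(mean(dz_span), mean(lat_ext))
    # invariants: positive radii, >= 2 centerline points, inside the field
    X <- (tiny_spec()$nx - 1) * tiny_spec()$spacing_um[1]
    Y <- (tiny_spec()$ny - 1) * tiny_spec()$spacing_um[2]
    expect_true(all(vv$radius_um > 0))
    expect_true(all(vapply(vv$centerline, nrow, 0L) >= 2))
    expect_true(all(vapply(vv$centerline, function(m) {
      all(m[, 1] >= 0 & m[, 1] <= X & m[, 2] >= 0 & m[, 2] <= Y)
    }, logical(1))))
  }
})

test_that("surface generation honours amplitude, seed, and correlation", {
  spec <- phantom_spec(surface_amplitude_um = 0)
  s0 <- generate_surface(spec)
  expect_true(all(s0 == spec$surface_mean_um)) # flat degenerate case

  spec2 <- phantom_spec(surface_amplitude_um = 30, surface_corr_um = 500)
  s1 <- generate_surface(spec2, seed = 9)
  s2 <- generate_surface(spec2, seed = 9)
  expect_identical(s1, s2) # determinism
  expect_lte(max(abs(s1 - mean(s1))), 30 + 1e-8)

  # empirical lateral correlation length within 2x of the requested 500 um
  acf_len <- function(field, d_um) {
    f <- field - mean(field)
    ac <- vapply(0:180, function(lag) {
      if (lag == 0) return(1)
      a <- f[1:(nrow(f) - lag), ]
      b <- f[(1 + lag):nrow(f), ]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, 0)
    first <- which(ac < exp(-1))[1]
    (first - 1) * d_um
  }
  len_x <- acf_len(s1, spec2$spacing_um[1])
  expect_gt(len_x, 250)
  expect_lt(len_x, 1000)
})

test_that("surface leaving the grid is an invalid-spec error", {
  expect_error(phantom_spec(surface_mean_um = 20, surface_amplitude_um = 40),
               class = "pamvasc_invalid_spec")
  expect_error(phantom_spec(pd_depth_um = 500, hd_depth_um = 100),
               class = "pamvasc_invalid_spec")
  expect_error(phantom_spec(timepoints_min = c(10, 20)),
               class = "pamvasc_invalid_spec")
})

test_that("rendering matches tube geometry without PSF and noise", {
  spec <- tiny_spec(noise_sd = 0, epidermis_intensity = 0,
                    surface_amplitude_um = 0)
  surf <- flat_surface(spec)

  # empty scene
  none <- place_vessels(tiny_spec(n_pd = 0L, n_rd = 0L, n_hd_pairs = 0L), 1)
  v0 <- render_volume(none, surf, spec, psf = FALSE, noise = FALSE)
  expect_true(all(v0$amplitude == 0))

  # one straight horizontal tube: suprathreshold voxel count close to the
  # analytic cylinder volume over the voxel volume
  r <- 30
  tube <- straight_tube(spec, depth_um = 200, radius_um = r)
  v1 <- render_volume(tube, surf, spec, psf = FALSE, noise = FALSE)
  count <- sum(v1$amplitude > 0.5)
  L <- (spec$ny - 1) * spec$spacing_um[2]
  analytic <- pi * r^2 * L / prod(spec$spacing_um)
  expect_lt(abs(count - analytic) / analytic, 0.10)

  # PSF broadens the axial profile of a thin tube by about the axial width
  thin <- straight_tube(spec, depth_um = 200, radius_um = 8)
  sharp <- render_volume(thin, surf, spec, psf = FALSE, noise = FALSE)
  blurred <- render_volume(thin, surf, spec, psf = TRUE, noise = FALSE)
  axial_fwhm <- function(vol, i, j) {
    a <- vol$amplitude[i, j, ]
    sum(a >= max(a) / 2) * spec$spacing_um[3]
  }
  i <- which(sharp$amplitude == max(sharp$amplitude), arr.ind = TRUE)[1, ]
  w0 <- axial_fwhm(sharp, i[1], i[2])
  w1 <- axial_fwhm(blurred, i[1], i[2])
  expect_gt(w1, w0 + 10) # grows by roughly the 30-um axial PSF
  expect_lt(w1, w0 + 60)
})

test_that("rendering is bit-identical for identical spec and seed", {
  spec <- tiny_spec(seed = 5L)
  a <- simulate_subject(spec, steroid_presets()$injection, seed = 5)
  b <- simulate_subject(spec, steroid_presets()$injection, seed = 5)
  expect_identical(a$volumes[[3]]$amplitude, b$volumes[[3]]$amplitude)
  expect_identical(a$surface, b$surface)
})

test_that("study generation yields group x subject x timepoint series", {
  spec <- tiny_spec()
  groups <- steroid_presets()[c("injection", "control")]
  subs <- generate_study(spec, groups, n_subjects = 2, seed = 4)
  expect_length(subs, 2 * 2)
  expect_length(subs[[1]]$volumes, length(spec$timepoints_min))
  # the full design (4 groups x 6 subjects x 7 timepoints) enumerates to 168
  expect_equal(length(steroid_presets()) * 6 * length(spec$timepoints_min),
               168)
  expect_error(
    generate_study(spec, list(a = list(), a = list()), n_subjects = 1),
    class = "pamvasc_invalid_groups")
})

test_that("ground truth area fractions follow tube geometry", {
  spec <- tiny_spec()
  truth0 <- phantom_truth(spec, place_vessels(tiny_spec(n_pd = 0L, n_rd = 0L,
                                                        n_hd_pairs = 0L), 1))
  expect_equal(ground_truth_layer_density(truth0, "PD"), 0)

  # lone tube r = 10 um spanning L = 1000 um in a 1000 x 1000 um field:
  # rectangle projection 2 r L / area = 0.02 (stadium caps add ~1.6%)
  field <- c(1000, 1000)
  tube <- tibble::tibble(
    vessel_id = 1L, layer = "PD", radius_um = 10, intensity = 1,
    centerline = list(cbind(c(500, 500), c(0, 1000), c(100, 100))))
  for (m in c("rect", "grid")) {
    frac <- projected_area_fraction(tube, field, method = m, cell_um = c(2, 2))
    expect_lt(abs(frac - 0.02) / 0.02, 0.03)
  }
  # halving the radius halves a lone tube's projection
  half <- tube
  half$radius_um <- 5
  expect_equal(projected_area_fraction(half, field, method = "rect") /
                 projected_area_fraction(tube, field, method = "rect"),
               0.5, tolerance = 0.02)

  expect_error(ground_truth_layer_density(truth0, "XX"),
               class = "pamvasc_unknown_layer")
})

test_that("oracle traces are constant without schedules, monotone with them", {
  spec <- tiny_spec()
  v <- place_vessels(spec, seed = 11)
  control <- phantom_truth(spec, v, list())
  tt <- truth_density_trace(control)
  expect_true(all(abs(tt$truth_relative - 1) < 1e-12))

  inj <- phantom_truth(spec, v, steroid_presets()$injection)
  ti <- truth_density_trace(inj)
  rd <- ti[ti$layer == "RD", ]
  expect_true(all(diff(rd$truth_frac) < 0)) # strictly decreasing
  for (l in c("PD", "HD")) {
    other <- ti[ti$layer == l, ]
    expect_true(all(abs(other$truth_relative - 1) < 1e-12))
  }
  # fractions stay within [0, 1] and are non-increasing wherever scheduled
  expect_true(all(ti$truth_frac >= 0 & ti$truth_frac <= 1))
})

test_that("scene conservation: layer subsets partition the vessel set", {
  v <- place_vessels(tiny_spec(), seed = 13)
  parts <- lapply(c("PD", "RD", "HD"), function(l) v$vessel_id[v$layer == l])
  expect_equal(sort(unlist(parts)), sort(v$vessel_id))
  expect_equal(sum(lengths(parts)), nrow(v)) # no vessel carries two tags
})

test_that("motion jitter displaces B-scans and is off by default", {
  spec0 <- tiny_spec(noise_sd = 0)
  spec1 <- tiny_spec(noise_sd = 0, motion_jitter_um = 9)
  surf <- flat_surface(spec0)
  v <- place_vessels(spec0, seed = 4)
  a <- render_volume(v, surf, spec0, noise_seed = 2, noise = FALSE)
  b <- render_volume(v, surf, spec1, noise_seed = 2, noise = FALSE)
  expect_false(identical(a$amplitude, b$amplitude))
  # jitter shifts whole B-scans: the detected surface varies between
  # B-scans (y) much more than within one (x)
  s <- detect_surface(b, median_window = 1, outlier_mad = NULL)
  between <- stats::sd(colMeans(s$z_index))
  within <- stats::median(apply(s$z_index, 2, stats::sd))
  expect_gt(between, 1)
  expect_gt(between, 2 * within)
})
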