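#' Place the phantom's vessel primitives
#'
#' Vessels are tubes around polyline centerlines in skin coordinates
#' (`x_um`, `y_um`, `depth_um` below the local surface). Three strata are
#' drawn to mimic skin anatomy: meandering near-horizontal capillaries in
#' the papillary band, near-vertical connectors spanning the papillary and
#' hypodermal bands through the reticular dermis, and long near-horizontal
#' arteriole-venule pairs in the hypodermal band.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed for the realisation; defaults to `spec$seed + 1`.
#' @return A tibble with one row per vessel: `vessel_id`, `layer`
#'   (`"PD"`, `"RD"`, `"HD"`), `radius_um`, `intensity`, and a `centerline`
#'   list-column of n x 3 matrices (`x_um`, `y_um`, `depth_um`).
#' @export
place_vessels <- function(spec, seed = spec$seed + 1L) {
  withr::with_seed(seed, place_vessels_impl(spec))
}

place_vessels_impl <- function(spec) {
  X <- (spec$nx - 1) * spec$spacing_um[1]
  Y <- (spec$ny - 1) * spec$spacing_um[2]
  rows <- list()

  add <- function(layer, cl, r, amp) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      layer = layer, radius_um = r, intensity = amp, centerline = list(cl))
  }
  ramp <- function() runif(1, spec$vessel_intensity[1], spec$vessel_intensity[2])

  # papillary capillaries: meandering walks in the shallow band
  for (v in seq_len(spec$n_pd)) {
    r <- runif(1, spec$pd_radius_um[1], spec$pd_radius_um[2])
    m <- r + 1
    L <- 0.8 * min(X, Y)
    step <- 40
    n <- max(2L, ceiling(L / step) + 1L)
    p <- matrix(0, n, 3)
    p[1, 1:2] <- c(runif(1, m, X - m), runif(1, m, Y - m))
    th <- runif(1, 0, 2 * pi)
    for (s in 2:n) {
      th <- th + rnorm(1, 0, 0.35)
      cand <- p[s - 1, 1:2] + step * c(cos(th), sin(th))
      # reflect the heading off the field margins
      if (cand[1] < m || cand[1] > X - m) {
        th <- pi - th
        cand <- p[s - 1, 1:2] + step * c(cos(th), sin(th))
      }
      if (cand[2] < m || cand[2] > Y - m) {
        th <- -th
        cand <- p[s - 1, 1:2] + step * c(cos(th), sin(th))
      }
      p[s, 1:2] <- pmin(pmax(cand, m), c(X, Y) - m)
    }
    z0 <- max(rnorm(1, spec$pd_depth_um, spec$pd_depth_sd_um), r + 5)
    wig <- cumsum(rnorm(n, 0, 1.5))
    band <- c(max(spec$pd_depth_um - 2 * spec$pd_depth_sd_um, r + 5),
              spec$pd_depth_um + 2 * spec$pd_depth_sd_um)
    p[, 3] <- pmin(pmax(z0 + wig - mean(wig), band[1]), band[2])
    add("PD", p, r, ramp())
  }

  # reticular connectors: near-vertical walks between the two bands
  for (v in seq_len(spec$n_rd)) {
    r <- runif(1, spec$rd_radius_um[1], spec$rd_radius_um[2])
    m <- r + 1
    # connectors traverse the reticular dermis between the two plexuses,
    # terminating where they anastomose with the plexus vessels
    top <- spec$pd_depth_um + 2 * spec$pd_depth_sd_um +
      max(spec$pd_radius_um) + 40
    bottom <- spec$hd_depth_um - 2 * spec$hd_depth_sd_um -
      max(spec$hd_radius_um) - 45
    if (bottom <= top) bottom <- top + 40
    depths <- seq(top, bottom, by = 40)
    if (tail(depths, 1) < bottom) depths <- c(depths, bottom)
    n <- length(depths)
    # per-step lateral sd such that the expected lateral path length
    # over the vertical span is about rd_drift_um (near-vertical tubes)
    sdxy <- spec$rd_drift_um / (1.25 * n)
    p <- matrix(0, n, 3)
    p[1, 1:2] <- c(runif(1, m, X - m), runif(1, m, Y - m))
    for (s in 2:n) {
      p[s, 1:2] <- pmin(pmax(p[s - 1, 1:2] + rnorm(2, 0, sdxy), m), c(X, Y) - m)
    }
    p[, 3] <- depths
    add("RD", p, r, ramp())
  }

  # hypodermal arteriole-venule pairs: long paired tubes along the longer axis
  for (v in seq_len(spec$n_hd_pairs)) {
    r1 <- runif(1, spec$hd_radius_um[1], spec$hd_radius_um[2])
    r2 <- min(max(r1 * runif(1, 1.0, 1.3), spec$hd_radius_um[1]),
              spec$hd_radius_um[2])
    along_y <- Y >= X
    sep <- 2.5 * r1
    m <- max(r1, r2) + sep + 1
    span <- if (along_y) Y else X
    u <- if (m < span - m) seq(m, span - m, by = 60) else
      seq(span * 0.1, span * 0.9, by = 60)
    n <- length(u)
    latmax <- if (along_y) X else Y
    lat0 <- if (m < latmax - m) runif(1, m, latmax - m) else latmax / 2
    meander <- cumsum(rnorm(n, 0, 4))
    meander <- meander - mean(meander)
    for (k in 1:2) {
      lat <- lat0 + (k - 1) * sep + meander
      lat <- pmin(pmax(lat, min(max(r1, r2) + 1, latmax / 2)),
                  max(latmax - max(r1, r2) - 1, latmax / 2))
      z0 <- rnorm(1, spec$hd_depth_um, spec$hd_depth_sd_um)
      p <- matrix(0, n, 3)
      if (along_y) {
        p[, 1] <- lat
        p[, 2] <- u
      } else {
        p[, 1] <- u
        p[, 2] <- lat
      }
      p[, 3] <- z0 + cumsum(rnorm(n, 0, 1)) - 0
      add("HD", p, if (k == 1) r1 else r2, ramp())
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(layer = character(), radius_um = numeric(),
                   intensity = numeric(), centerline = list())
  out$vessel_id <- seq_len(nrow(out))
  dplyr::select(out, "vessel_id", "layer", "radius_um", "intensity",
                "centerline")
}

#' Apply layer constriction schedules to a vessel set
#'
#' Scales each vessel's radius by its layer's [constriction_factor()] at
#' time `t_min`. Layers without a schedule are unchanged; at `t_min = 0`
#' the vessel set is returned identical.
#'
#' @param vessels Vessel tibble from [place_vessels()].
#' @param schedules Named list of [constriction_schedule()]s keyed by layer
#'   tag (`"PD"`, `"RD"`, `"HD"`); may be empty.
#' @param t_min Time in minutes, `>= 0`.
#' @return The vessel tibble with scaled `radius_um`.
#' @export
apply_constriction <- function(vessels, schedules, t_min) {
  if (t_min < 0) pam_abort("t_min must be >= 0", "invalid_time")
  bad <- setdiff(names(schedules), LAYERS)
  if (length(bad)) {
    pam_abort(paste0("unknown layer tag in schedules: ", bad[1]),
              "unknown_layer")
  }
  fac <- vapply(vessels$layer, function(l) {
    constriction_factor(schedules[[l]], t_min)
  }, numeric(1), USE.NAMES = FALSE)
  vessels$radius_um <- vessels$radius_um * fac
  vessels
}
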