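# independent brute-force window count: explicit loop over cones
brute_count <- function(x_arcmin, y_arcmin, cx, cy, radius) {
  n <- 0L
  for (i in seq_along(x_arcmin)) {
    if (sqrt((x_arcmin[i] - cx)^2 + (y_arcmin[i] - cy)^2) <= radius)
      n <- n + 1L
  }
  n
}

# ideal hexagonal lattice over a square field, spacing in arcmin
hex_lattice_mosaic <- function(spacing, extent_arcmin, ppa = 9.48, rmf = NULL) {
  dy <- spacing * sqrt(3) / 2
  ys <- seq(0, extent_arcmin, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(off, extent_arcmin, by = spacing)
    cbind(xs, ys[i])
  }))
  cone_mosaic(pts[, 1] * ppa, pts[, 2] * ppa, pixels_per_arcmin = ppa,
              rmf = rmf, width_px = extent_arcmin * ppa,
              height_px = extent_arcmin * ppa)
}

# eye model from an explicit surface table (for closed-form checks)
raw_eye_model <- function(z, radius, n_before, n_after, total) {
  structure(list(surfaces = data.frame(z_mm = z, radius_mm = radius,
                                       n_before = n_before, n_after = n_after),
                 total_axial_length = total),
            class = "eye_model")
}

table2 <- table2_cohort()
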