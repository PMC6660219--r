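test_that("window counts match the brute-force all-pairs oracle exactly", {
  set.seed(42)
  for (n in c(50, 800, 3000)) {
    ext <- 400  # arcmin; sparse enough to avoid duplicate-label tripwires
    x <- runif(n, 0, ext)
    y <- runif(n, 0, ext)
    m <- cone_mosaic(x * 9.48, y * 9.48, width_px = ext * 9.48,
                     height_px = ext * 9.48)
    centers <- cbind(runif(5, 50, ext - 50), runif(5, 50, ext - 50))
    wd <- window_density(m, centers, diameter_arcmin = 10)
    for (j in 1:5)
      expect_identical(wd$n[j], brute_count(x, y, centers[j, 1],
                                            centers[j, 2], 5))
  }
})

test_that("single-cone and empty windows give the closed-form densities", {
  empty <- cone_mosaic(numeric(0), numeric(0), width_px = 200, height_px = 200)
  expect_equal(window_density(empty, c(10, 10))$d_ang, 0)
  one <- cone_mosaic(10 * 9.48, 10 * 9.48, width_px = 200, height_px = 200)
  wd <- window_density(one, c(10, 10), diameter_arcmin = 10)
  expect_equal(wd$d_ang, 1 / (pi * (5 / 60)^2), tolerance = 1e-12)  # 45.84
})

test_that("a cone exactly on the window boundary is counted", {
  ppa <- 10
  m <- cone_mosaic(c(150, 200), c(100, 100), pixels_per_arcmin = ppa,
                   width_px = 300, height_px = 200)
  # centre at (10, 10) arcmin; cones at 5 and 10 arcmin distance
  expect_equal(window_density(m, c(10, 10), diameter_arcmin = 10)$n, 1)
  expect_equal(window_density(m, c(10, 10), diameter_arcmin = 20)$n, 2)
})

test_that("an ideal hexagonal lattice measures at its closed-form density", {
  s <- 0.5
  m <- hex_lattice_mosaic(s, extent_arcmin = 30, rmf = 280)
  wd <- window_density(m, c(15, 15), diameter_arcmin = 10)
  d_true <- 2 / (sqrt(3) * (s / 60)^2)   # ~16,628 cones/deg^2
  expect_equal(wd$d_ang, d_true, tolerance = 0.02)
  expect_true(wd$valid)
})

test_that("angular and linear densities are mutually consistent through the RMF", {
  m <- hex_lattice_mosaic(0.6, extent_arcmin = 20, rmf = 291.3)
  wd <- window_density(m, c(10, 10))
  expect_equal(wd$d_lin * (m$rmf / 1000)^2, wd$d_ang, tolerance = 1e-12)
  expect_equal(convert_density(convert_density(123, 280, "ang_to_lin"),
                               280, "lin_to_ang"), 123, tolerance = 1e-12)
  expect_equal(convert_density(5, 1000, "ang_to_lin"), 5)
  # published PRL angular and linear columns agree exactly through the
  # published RMF (same location, pure unit conversion) ...
  implied_prl <- convert_density(table2$prl_density_deg2,
                                 table2$rmf_um_per_deg, "ang_to_lin")
  expect_lt(max(abs(implied_prl - table2$prl_density_mm2) /
                  table2$prl_density_mm2), 0.003)
  # ... while the peak columns differ by up to ~1.6%: the angular and linear
  # maps each report their own peak location, which need not coincide
  implied <- convert_density(table2$peak_density_deg2,
                             table2$rmf_um_per_deg, "ang_to_lin")
  expect_lt(max(abs(implied - table2$peak_density_mm2) /
                  table2$peak_density_mm2), 0.02)
})

test_that("windows crossing the image edge are flagged invalid, not truncated", {
  m <- hex_lattice_mosaic(1, extent_arcmin = 20)
  wd <- window_density(m, c(2, 10), diameter_arcmin = 10)
  expect_false(wd$valid)
  expect_true(window_density(m, c(10, 10), diameter_arcmin = 10)$valid)
})

test_that("density map of a uniform mosaic is flat and of an empty mosaic zero", {
  prof <- density_profile(12000, r0_arcmin = 1e6, gamma = 1.2, anisotropy = 1)
  m <- generate_mosaic(prof, extent_arcmin = 24, seed = 7, rmf = 290)
  map <- density_map(m, step_px = 8)
  vals <- map$d_ang[map$valid]
  expect_lt(stats::sd(vals) / mean(vals), 0.05)
  empty <- cone_mosaic(numeric(0), numeric(0), width_px = 100, height_px = 100)
  map0 <- density_map(empty, step_px = 10)
  expect_true(all(map0$d_ang == 0))
  expect_error(density_map(m, step_px = 0), "positive")
})

test_that("peak finding recovers an injected peak and breaks ties by centroid", {
  prof <- density_profile(15000, r0_arcmin = 30, gamma = 2, anisotropy = 1)
  m <- generate_mosaic(prof, extent_arcmin = 50, seed = 11, rmf = 290)
  map <- density_map(m, step_px = 6)
  pk <- find_peak(map)
  expect_equal(pk$d_ang, 15000, tolerance = 0.05)
  expect_lt(sqrt(sum((pk$location_arcmin - c(25, 25))^2)), 5)
  # constant map: every valid cell ties, peak at the valid-region centroid
  empty <- cone_mosaic(numeric(0), numeric(0), width_px = 200, height_px = 200)
  mapc <- density_map(empty, step_px = 20, diameter_arcmin = 2)
  pc <- find_peak(mapc)
  expect_equal(pc$location_px, c(100, 100))
  expect_error(find_peak(density_map(empty, step_px = 20,
                                     diameter_arcmin = 50)), "no valid cells")
})

test_that("map values fall monotonically with eccentricity on a radial mosaic", {
  prof <- density_profile(15000, r0_arcmin = 20, gamma = 1.2, anisotropy = 1)
  m <- generate_mosaic(prof, extent_arcmin = 50, seed = 3, rmf = 290)
  map <- density_map(m, step_px = 6)
  ecc <- sqrt(outer((map$x_px / 9.48 - 25)^2, (map$y_px / 9.48 - 25)^2, "+"))
  sel <- map$valid & ecc > 5
  expect_lt(stats::cor(ecc[sel], map$d_ang[sel], method = "spearman"), -0.95)
})

test_that("annular profile obeys the inner-exclusive outer-inclusive rule", {
  ppa <- 10
  # cones at distances 0, 5 (on first edge) and 7 arcmin from the centre
  m <- cone_mosaic(c(100, 150, 170), c(100, 100, 100), pixels_per_arcmin = ppa,
                   width_px = 300, height_px = 200)
  pr <- annular_profile(m, c(10, 10), width = 5, unit = "arcmin",
                        max_eccentricity = 10)
  expect_equal(pr$n, c(2L, 1L))   # the 5-arcmin cone joins the innermost disk
})

test_that("annular profiles recover uniform and radial generator truth", {
  prof <- density_profile(12000, r0_arcmin = 1e6, gamma = 1.2, anisotropy = 1)
  m <- generate_mosaic(prof, extent_arcmin = 30, seed = 5, rmf = 290)
  pr <- annular_profile(m, c(15, 15), width = 5, max_eccentricity = 15)
  expect_true(all(abs(pr$d_ang[pr$valid] - 12000) / 12000 < 0.05))
  # empty mosaic: all-zero profile
  empty <- cone_mosaic(numeric(0), numeric(0), width_px = 300, height_px = 300)
  expect_true(all(annular_profile(empty, c(15, 15), width = 5,
                                  max_eccentricity = 15)$d_ang == 0))
  # radial falloff: non-increasing beyond the first annulus
  prof2 <- density_profile(15000, r0_arcmin = 15, gamma = 1.5, anisotropy = 1)
  m2 <- generate_mosaic(prof2, extent_arcmin = 60, seed = 6, rmf = 290)
  pr2 <- annular_profile(m2, c(30, 30), width = 5, max_eccentricity = 30)
  expect_true(all(diff(pr2$d_ang[-1]) < 0))
  # micron-unit annuli agree with arcmin annuli at matched radii
  pr_um <- annular_profile(m2, c(30, 30), width = 25, unit = "um",
                           max_eccentricity = 100)
  expect_true(all(pr_um$d_lin >= 0))
})

test_that("meridional profiles detect anisotropy and collapse at step 0", {
  iso <- generate_mosaic(density_profile(14000, 25, 1.5, anisotropy = 1),
                         extent_arcmin = 50, seed = 8, rmf = 290)
  h <- directional_profile(iso, c(25, 25), "horizontal", step_arcmin = 5,
                           max_eccentricity = 15)
  v <- directional_profile(iso, c(25, 25), "vertical", step_arcmin = 5,
                           max_eccentricity = 15)
  expect_true(all(abs(h$d_ang - v$d_ang) / pmax(h$d_ang, v$d_ang) < 0.05))
  an <- generate_mosaic(density_profile(14000, 25, 1.5, anisotropy = 1.6),
                        extent_arcmin = 50, seed = 9, rmf = 290)
  hv <- directional_profile(an, c(25, 25), "horizontal", step_arcmin = 15,
                            max_eccentricity = 15)
  vv <- directional_profile(an, c(25, 25), "vertical", step_arcmin = 15,
                            max_eccentricity = 15)
  # steeper vertical falloff: off-centre vertical density below horizontal
  expect_lt(mean(vv$d_ang[c(1, 3)]), mean(hv$d_ang[c(1, 3)]))
  p0 <- directional_profile(iso, c(25, 25), "horizontal", step_arcmin = 0)
  expect_equal(nrow(p0), 1)
  expect_equal(p0$d_ang, window_density(iso, c(25, 25))$d_ang)
})

test_that("near-duplicate cone labels are rejected", {
  expect_error(cone_mosaic(c(100, 100.1), c(50, 50), pixels_per_arcmin = 9.48),
               "0.05 arcmin")
})

test_that("micron-window mode stays close to the angular window", {
  m <- hex_lattice_mosaic(0.6, extent_arcmin = 20, rmf = 300)
  a <- window_density(m, c(10, 10), unit_mode = "angular")
  u <- window_density(m, c(10, 10), unit_mode = "micron")
  # at rmf exactly 300 the two windows coincide
  expect_equal(a$d_ang, u$d_ang, tolerance = 1e-12)
  m2 <- hex_lattice_mosaic(0.6, extent_arcmin = 20, rmf = 270)
  u2 <- window_density(m2, c(10, 10), unit_mode = "micron")
  expect_equal(u2$d_ang, a$d_ang, tolerance = 0.05)
})
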