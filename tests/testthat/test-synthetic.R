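test_that("mosaic generation is deterministic given the seed", {
  prof <- density_profile(13000, 25, 1.2)
  m1 <- generate_mosaic(prof, extent_arcmin = 15, seed = 41)
  m2 <- generate_mosaic(prof, extent_arcmin = 15, seed = 41)
  expect_identical(m1$x_px, m2$x_px)
  expect_identical(m1$y_px, m2$y_px)
  m3 <- generate_mosaic(prof, extent_arcmin = 15, seed = 42)
  expect_false(identical(m1$x_px, m3$x_px))
})

test_that("generated mosaics achieve the requested density profile", {
  # constant profile: window density within 5% of the target
  prof <- density_profile(15000, r0_arcmin = 1e6, gamma = 1.2, anisotropy = 1)
  m <- generate_mosaic(prof, extent_arcmin = 24, seed = 43, rmf = 290)
  wd <- window_density(m, c(12, 12))
  expect_equal(wd$d_ang, 15000, tolerance = 0.05)
  # radial profile: annular densities track D(r) within 5% well inside field
  prof2 <- density_profile(16000, r0_arcmin = 30, gamma = 1.2, anisotropy = 1)
  m2 <- generate_mosaic(prof2, extent_arcmin = 60, seed = 44, rmf = 290)
  pr <- annular_profile(m2, c(30, 30), width = 5, max_eccentricity = 25)
  # ground truth: area-weighted mean of D(r) over each annulus
  truth <- vapply(seq_len(nrow(pr)), function(i) {
    f <- function(r) profile_density(prof2, r) * 2 * pi * r
    stats::integrate(f, pr$inner[i], pr$outer[i])$value /
      (pi * (pr$outer[i]^2 - pr$inner[i]^2))
  }, numeric(1))
  expect_true(all(abs(pr$d_ang - truth) / truth < 0.05))
})

test_that("densities implying sub-resolution spacing are refused", {
  expect_error(generate_mosaic(density_profile(3e6), extent_arcmin = 5),
               "0.05 arcmin")
})

test_that("fixation traces are seeded Gaussians with convergent covariance", {
  tr <- generate_fixation_trace(c(1, 2), matrix(c(2, 0.5, 0.5, 1), 2),
                                n = 20000, seed = 45)
  S <- stats::cov(cbind(tr$x, tr$y))
  expect_equal(S, matrix(c(2, 0.5, 0.5, 1), 2), tolerance = 0.05,
               ignore_attr = TRUE)
  zero <- generate_fixation_trace(c(3, -1), matrix(0, 2, 2), n = 50, seed = 46)
  expect_true(all(zero$x == 3) && all(zero$y == -1))
  expect_error(generate_fixation_trace(c(0, 0), matrix(c(1, 2, 2, 1), 2),
                                       n = 10), "semi-definite")
  t1 <- generate_fixation_trace(n = 500, seed = 47)
  t2 <- generate_fixation_trace(n = 500, seed = 47)
  expect_identical(t1$x, t2$x)
})

test_that("noiseless cohorts carry the growth-model signatures by construction", {
  ge <- generate_cohort(growth_model("global_expansion"), n_eyes = 20, seed = 48)
  regs <- cohort_regressions(ge)
  expect_equal(regs$peak_ang$slope, 0, tolerance = 1e-9)
  expect_lt(regs$peak_lin$slope, 0)
  es <- generate_cohort(growth_model("equatorial_stretching"), n_eyes = 20,
                        seed = 48)
  regs2 <- cohort_regressions(es)
  expect_lt(abs(regs2$peak_lin$slope), 1e-6)
  expect_gt(regs2$peak_ang$slope, 0)
  od <- generate_cohort(growth_model("over_development", gain = 0.05),
                        n_eyes = 20, seed = 48)
  regs3 <- cohort_regressions(od)
  expect_gt(regs3$peak_lin$slope, 0)
  expect_gt(regs3$peak_ang$slope, regs2$peak_ang$slope)
  # mixed model interpolates: intermediate positive angular slope
  mx <- generate_cohort(growth_model("mixed", mix = 0.5), n_eyes = 20,
                        seed = 48)
  regs4 <- cohort_regressions(mx)
  expect_gt(regs4$peak_ang$slope, 0)
  expect_lt(regs4$peak_ang$slope, regs2$peak_ang$slope)
  expect_lt(regs4$peak_lin$slope, 0)
})

test_that("cohort tables are schema-complete, unit-consistent and seeded", {
  co <- generate_cohort(growth_model("mixed", mix = 0.4), n_eyes = 28,
                        noise_sd = 0.08, seed = 49)
  expect_equal(nrow(co), 28)
  expect_true(all(c("subject", "eye", "axial_length_mm", "rmf_um_per_deg",
                    "peak_density_deg2", "peak_density_mm2",
                    "prl_dist_arcmin", "prl_dist_um",
                    "prl_density_deg2", "prl_density_mm2") %in% names(co)))
  expect_equal(convert_density(co$peak_density_deg2, co$rmf_um_per_deg,
                               "ang_to_lin"), co$peak_density_mm2,
               tolerance = 1e-12)
  expect_equal(co$prl_dist_um, co$prl_dist_arcmin * co$rmf_um_per_deg / 60,
               tolerance = 1e-12)
  expect_true(all(co$axial_length_mm >= 22.2 & co$axial_length_mm <= 27.1))
  co2 <- generate_cohort(growth_model("mixed", mix = 0.4), n_eyes = 28,
                         noise_sd = 0.08, seed = 49)
  expect_identical(co, co2)
  expect_error(generate_cohort(growth_model("mixed"), n_eyes = 4), "at least 6")
  expect_error(generate_cohort(growth_model("mixed"), al_range = c(19, 27)),
               "al_range")
})

test_that("a moderate noisy replicate set recovers the injected angular slope", {
  gm <- growth_model("mixed", mix = 0.42)
  fits <- numeric(20)
  truths <- numeric(20)
  for (i in 1:20) {
    co <- generate_cohort(gm, n_eyes = 28, noise_sd = 0.08, seed = 500 + i)
    fits[i] <- ols_fit(co$axial_length_mm, co$peak_density_deg2)$slope
    truths[i] <- attr(co, "true_slope_ang")
  }
  expect_equal(mean(fits / truths), 1, tolerance = 0.15)
})
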