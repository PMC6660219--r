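#' Radially decreasing cone density profile
#'
#' Parametric ground-truth profile for synthetic mosaics:
#' D(r) = peak / (1 + (r / r0)^gamma), with an elliptical eccentricity
#' r = sqrt(x^2 + (anisotropy * y)^2) so that density falls off faster
#' vertically when `anisotropy > 1`, echoing the steeper superior/inferior
#' falloff of real foveas. A convention for testing, not a biological model.
#'
#' @param peak_density_deg2 Central density, cones/deg^2.
#' @param r0_arcmin Half-density radius, arcmin.
#' @param gamma Falloff exponent.
#' @param anisotropy Vertical/horizontal falloff ratio (> 1 = steeper
#'   vertical).
#' @return Object of class `density_profile`.
#' @export
density_profile <- function(peak_density_deg2 = 15000, r0_arcmin = 30,
                            gamma = 1.2, anisotropy = 1.15) {
  stopifnot(peak_density_deg2 > 0, r0_arcmin > 0, gamma > 0, anisotropy > 0)
  structure(list(peak = peak_density_deg2, r0 = r0_arcmin,
                 gamma = gamma, anisotropy = anisotropy),
            class = "density_profile")
}

#' Evaluate a density profile
#'
#' @param profile A [density_profile()].
#' @param x,y Offsets from the profile centre in arcmin.
#' @return Density in cones/deg^2.
#' @export
profile_density <- function(profile, x, y = 0) {
  stopifnot(inherits(profile, "density_profile"))
  r <- sqrt(x^2 + (profile$anisotropy * y)^2)
  profile$peak / (1 + (r / profile$r0)^profile$gamma)
}

# hexagonal-lattice centre-to-centre spacing (arcmin) at density D (deg^-2)
.hex_spacing_arcmin <- function(d_deg2) 60 * sqrt(2 / (sqrt(3) * d_deg2))

# min-distance calibration: dart throwing at 30 attempts/candidate with
# min distance = .PACKING * hex spacing reproduces the target density
# (measured once on constant profiles; see the methods vignette)
.PACKING <- 0.865

#' Generate a quasi-hexagonal cone mosaic
#'
#' Variable-density dart throwing: candidate points are drawn uniformly over
#' a square field, sorted by eccentricity for progressive fill, and accepted
#' when no previously accepted cone lies within a minimum distance tied to
#' the local target spacing. The result is a blue-noise, quasi-hexagonal
#' point set whose local density tracks the requested profile to within a
#' few percent.
#'
#' @param profile A [density_profile()]; its centre sits at the field centre.
#' @param extent_arcmin Side of the square field, arcmin (at least ~4 r0 is
#'   recommended so the falloff is visible).
#' @param seed Integer seed; the same seed reproduces the same mosaic.
#' @param pixels_per_arcmin Image scale for the returned mosaic.
#' @param rmf Optional RMF attached to the mosaic.
#' @param eye_id Optional identifier.
#' @param attempts_per_point Candidate budget per expected cone.
#' @return A [cone_mosaic()] whose image spans
#'   `extent_arcmin * pixels_per_arcmin` pixels.
#' @examples
#' m <- generate_mosaic(density_profile(12000), extent_arcmin = 15, seed = 1)
#' @export
generate_mosaic <- function(profile, extent_arcmin = 40, seed = 1,
                            pixels_per_arcmin = 9.48, rmf = NULL,
                            eye_id = NULL, attempts_per_point = 30) {
  stopifnot(inherits(profile, "density_profile"), extent_arcmin > 0)
  if (.PACKING * .hex_spacing_arcmin(profile$peak) < 0.05)
    stop("requested density implies cone spacing below 0.05 arcmin")
  set.seed(seed)
  half <- extent_arcmin / 2
  dfun <- function(x, y) profile_density(profile, x, y)   # deg^-2
  # candidate budget scaled by the PEAK density so the densest region still
  # receives the full per-point attempt budget (uniform candidates would
  # starve it and leave the centre under-packed)
  m_cand <- ceiling(attempts_per_point * profile$peak *
                      (extent_arcmin / 60)^2)
  cx <- stats::runif(m_cand, -half, half)
  cy <- stats::runif(m_cand, -half, half)
  ord <- order(cx^2 + (profile$anisotropy * cy)^2)
  cx <- cx[ord]; cy <- cy[ord]
  min_d <- .PACKING * .hex_spacing_arcmin(dfun(cx, cy))
  # background grid for neighbour lookup, cell = largest min distance
  h <- max(min_d)
  ncell <- max(1L, ceiling(extent_arcmin / h))
  ci <- pmin(ncell - 1L, pmax(0L, floor((cx + half) / h)))
  cj <- pmin(ncell - 1L, pmax(0L, floor((cy + half) / h)))
  grid <- vector("list", ncell * ncell)
  ax <- numeric(m_cand); ay <- numeric(m_cand); na <- 0L
  for (k in seq_len(m_cand)) {
    ii <- ci[k]; jj <- cj[k]
    ok <- TRUE
    for (di in -1:1) {
      i2 <- ii + di
      if (i2 < 0L || i2 >= ncell) next
      for (dj in -1:1) {
        j2 <- jj + dj
        if (j2 < 0L || j2 >= ncell) next
        idx <- grid[[i2 + ncell * j2 + 1L]]
        if (length(idx) &&
            any((ax[idx] - cx[k])^2 + (ay[idx] - cy[k])^2 < min_d[k]^2)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      na <- na + 1L
      ax[na] <- cx[k]; ay[na] <- cy[k]
      g <- ii + ncell * jj + 1L
      grid[[g]] <- c(grid[[g]], na)
    }
  }
  cone_mosaic((ax[seq_len(na)] + half) * pixels_per_arcmin,
              (ay[seq_len(na)] + half) * pixels_per_arcmin,
              pixels_per_arcmin = pixels_per_arcmin, rmf = rmf,
              eye_id = eye_id,
              width_px = extent_arcmin * pixels_per_arcmin,
              height_px = extent_arcmin * pixels_per_arcmin)
}

#' Generate a synthetic fixation trace
#'
#' Bivariate Gaussian fixation scatter with a given centroid and covariance.
#'
#' @param centroid Mean position `c(x, y)`, arcmin.
#' @param covariance 2x2 positive semi-definite matrix, arcmin^2.
#' @param n Number of frames.
#' @param seed Integer seed.
#' @param eye_id Optional identifier.
#' @return A [fixation_trace()].
#' @export
generate_fixation_trace <- function(centroid = c(0, 0),
                                    covariance = diag(2), n = 1000,
                                    seed = 1, eye_id = NULL) {
  covariance <- as.matrix(covariance)
  stopifnot(all(dim(covariance) == 2), n >= 1)
  if (max(abs(covariance - t(covariance))) > 1e-12 ||
      any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("covariance must be symmetric positive semi-definite")
  set.seed(seed)
  if (all(covariance == 0)) {
    xy <- matrix(rep(centroid, each = n), ncol = 2)
  } else {
    xy <- MASS::mvrnorm(n, mu = centroid, Sigma = covariance)
    if (n == 1) xy <- matrix(xy, ncol = 2)
  }
  fixation_trace(xy[, 1], xy[, 2], eye_id = eye_id)
}

#' Specify a myopic eye-growth model
#'
#' Encodes how foveal cone density co-varies with axial length in a
#' simulated cohort. `"global_expansion"`: the retina stretches in
#' proportion to eye length, so angular density is constant and linear
#' density falls. `"equatorial_stretching"`: the fovea is spared, linear
#' density is constant and angular density rises. `"over_development"`:
#' packing at the fovea keeps increasing, so linear density grows as
#' exp(gain * (AL - 23.5)) and angular density rises faster still.
#' `"mixed"` interpolates between the first two on the log-density scale
#' (`mix = 0` is global expansion, `mix = 1` equatorial stretching), the
#' regime real cohorts appear to occupy.
#'
#' @param kind Growth-model kind.
#' @param baseline_bio [biometry()] of the baseline (AL 23.5 mm) eye; its
#'   anterior segment is held fixed across the cohort.
#' @param baseline_density_deg2 Angular density of the baseline eye.
#' @param profile [density_profile()] used for PRL-eccentricity bookkeeping
#'   (and any generated mosaics).
#' @param gain d log(linear density) / d AL for `"over_development"`, 1/mm.
#' @param mix Interpolation weight for `"mixed"`.
#' @return Object of class `growth_model`.
#' @export
growth_model <- function(kind = c("global_expansion", "equatorial_stretching",
                                  "over_development", "mixed"),
                         baseline_bio = biometry(23.5, 7.8, 3.6),
                         baseline_density_deg2 = 14500,
                         profile = density_profile(baseline_density_deg2),
                         gain = 0.05, mix = 0.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(baseline_bio, "biometry"), baseline_density_deg2 > 0)
  if (kind == "over_development" && gain <= 0)
    stop("over_development requires a positive gain")
  if (kind == "mixed" && (mix < 0 || mix > 1))
    stop("mix must lie in [0, 1]")
  structure(list(kind = kind, baseline_bio = baseline_bio,
                 baseline_density_deg2 = baseline_density_deg2,
                 profile = profile, gain = gain, mix = mix),
            class = "growth_model")
}

#' Generate a synthetic per-eye cohort under a growth model
#'
#' Draws axial lengths uniformly over a range, computes each eye's RMF by
#' the four-surface ray trace with the anterior segment held at the
#' baseline biometry, sets noiseless peak densities according to the growth
#' model, and applies multiplicative log-normal measurement noise (one
#' factor per eye, so angular and linear densities stay mutually
#' consistent). PRL displacement is drawn from a Rayleigh distribution and
#' the PRL density follows the falloff profile at that eccentricity.
#'
#' @param model A [growth_model()].
#' @param n_eyes Number of eyes (>= 6); consecutive pairs share a subject id.
#' @param al_range Axial-length range in mm, within (20, 30).
#' @param noise_sd SD of the log-normal density noise (fractional; 0 = none).
#' @param seed Integer seed.
#' @param prl_sigma_arcmin Rayleigh scale of the PRL displacement.
#' @return Cohort data frame in the packaged fixture schema, with attributes
#'   `seed`, `model`, and `true_slope_ang` / `true_slope_lin` — the OLS
#'   slopes of the noiseless densities on axial length (the injected ground
#'   truth for recovery experiments).
#' @examples
#' co <- generate_cohort(growth_model("mixed", mix = 0.4), n_eyes = 10, seed = 2)
#' @export
generate_cohort <- function(model, n_eyes = 28, al_range = c(22.2, 27.1),
                            noise_sd = 0, seed = 1,
                            prl_sigma_arcmin = 4.87) {
  stopifnot(inherits(model, "growth_model"))
  if (n_eyes < 6) stop("n_eyes must be at least 6")
  if (al_range[1] <= 20 || al_range[2] >= 30 || al_range[1] >= al_range[2])
    stop("al_range must be increasing and lie within (20, 30) mm")
  set.seed(seed)
  al <- sort(stats::runif(n_eyes, al_range[1], al_range[2]))
  bb <- model$baseline_bio
  rmf <- vapply(al, function(a)
    rmf_from_biometry(biometry(a, bb$corneal_radius, bb$acd))$rmf_um_per_deg,
    numeric(1))
  rmf0 <- rmf_from_biometry(bb)$rmf_um_per_deg
  d_ang0 <- model$baseline_density_deg2
  d_lin0 <- convert_density(d_ang0, rmf0, "ang_to_lin")
  d_ang <- switch(model$kind,
    global_expansion = rep(d_ang0, n_eyes),
    equatorial_stretching = convert_density(d_lin0, rmf, "lin_to_ang"),
    over_development = convert_density(
      d_lin0 * exp(model$gain * (al - bb$axial_length)), rmf, "lin_to_ang"),
    mixed = d_ang0 * (rmf / rmf0)^(2 * model$mix))
  d_lin <- convert_density(d_ang, rmf, "ang_to_lin")
  true_slope_ang <- unname(stats::coef(stats::lm(d_ang ~ al))[2])
  true_slope_lin <- unname(stats::coef(stats::lm(d_lin ~ al))[2])
  noise <- if (noise_sd > 0) exp(stats::rnorm(n_eyes, 0, noise_sd)) else
    rep(1, n_eyes)
  prl_dist <- prl_sigma_arcmin * sqrt(-2 * log(stats::runif(n_eyes)))
  prl_factor <- profile_density(model$profile, prl_dist) / model$profile$peak
  cohort <- data.frame(
    subject = sprintf("S%03d", rep(seq_len(ceiling(n_eyes / 2)), each = 2)[seq_len(n_eyes)]),
    eye = rep(c("R", "L"), length.out = n_eyes),
    axial_length_mm = al,
    corneal_radius_mm = bb$corneal_radius,
    acd_mm = bb$acd,
    rmf_um_per_deg = rmf,
    peak_density_deg2 = d_ang * noise,
    peak_density_mm2 = d_lin * noise,
    prl_dist_arcmin = prl_dist,
    prl_dist_um = prl_dist * rmf / 60,
    prl_density_deg2 = d_ang * noise * prl_factor,
    prl_density_mm2 = d_lin * noise * prl_factor)
  attr(cohort, "seed") <- seed
  attr(cohort, "model") <- model
  attr(cohort, "true_slope_ang") <- true_slope_ang
  attr(cohort, "true_slope_lin") <- true_slope_lin
  attr(cohort, "noiseless_density_deg2") <- d_ang
  attr(cohort, "noiseless_density_mm2") <- d_lin
  cohort
}
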