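#' Per-subject ocular biometry
#'
#' Bundle the three biometric measurements needed to build a personalised
#' schematic eye: axial length, front corneal radius of curvature and
#' anterior chamber depth (corneal front apex to lens front apex, the
#' IOLMaster convention).
#'
#' @param axial_length Axial length in mm (corneal apex to retina).
#' @param corneal_radius Front corneal radius of curvature in mm.
#' @param acd Anterior chamber depth in mm, measured from the corneal front
#'   apex to the lens front surface.
#' @param spherical_equivalent Optional spherical equivalent refraction in
#'   dioptres; carried as metadata only.
#' @return An object of class `biometry`.
#' @examples
#' biometry(23.30, 7.80, 3.12)
#' @export
biometry <- function(axial_length, corneal_radius, acd,
                     spherical_equivalent = NA_real_) {
  stopifnot(is.numeric(axial_length), is.numeric(corneal_radius),
            is.numeric(acd), length(axial_length) == 1L)
  if (!is.finite(axial_length) || axial_length <= 15 || axial_length >= 40)
    stop("invalid biometry: axial_length must lie in (15, 40) mm, got ",
         axial_length)
  if (!is.finite(corneal_radius) || corneal_radius <= 0)
    stop("invalid biometry: corneal_radius must be positive, got ",
         corneal_radius)
  if (!is.finite(acd) || acd <= 0 || acd >= axial_length)
    stop("invalid biometry: acd must lie in (0, axial_length), got ", acd)
  structure(list(axial_length = axial_length,
                 corneal_radius = corneal_radius,
                 acd = acd,
                 spherical_equivalent = spherical_equivalent),
            class = "biometry")
}

#' Schematic-eye constants
#'
#' Fixed optical constants completing the four-surface schematic eye around
#' the measured biometry. Refractive indices, lens radii and element
#' thicknesses follow the Gullstrand exact schematic eye, with two
#' adaptations: the back corneal radius is tied to the measured front radius
#' (88.31% of it, the Gullstrand ratio), and the crystalline lens is treated
#' as a homogeneous equivalent-index element. The equivalent lens index
#' (default 1.400) is this package's calibrated Gullstrand-variant constant;
#' see the methods vignette for how it was fixed.
#'
#' @param corneal_back_fraction Back/front corneal radius ratio.
#' @param n_cornea,n_aqueous,n_lens,n_vitreous Refractive indices of the
#'   cornea, aqueous humour, equivalent lens and vitreous humour.
#' @param corneal_thickness Central corneal thickness in mm.
#' @param lens_thickness Axial lens thickness in mm.
#' @param lens_front_radius,lens_back_radius Lens surface radii in mm,
#'   signed: light travels +z and a radius is positive when the centre of
#'   curvature lies to the right of the vertex.
#' @return An object of class `schematic_constants`.
#' @export
schematic_constants <- function(corneal_back_fraction = 0.8831,
                                n_cornea = 1.376,
                                n_aqueous = 1.336,
                                n_lens = 1.400,
                                n_vitreous = 1.336,
                                corneal_thickness = 0.5,
                                lens_thickness = 3.6,
                                lens_front_radius = 10.0,
                                lens_back_radius = -6.0) {
  if (corneal_back_fraction <= 0 || corneal_back_fraction > 1)
    stop("corneal_back_fraction must lie in (0, 1]")
  idx <- c(n_cornea, n_aqueous, n_lens, n_vitreous)
  if (any(!is.finite(idx)) || any(idx <= 1))
    stop("all media indices must exceed 1")
  if (corneal_thickness <= 0 || lens_thickness <= 0)
    stop("element thicknesses must be positive")
  structure(list(corneal_back_fraction = corneal_back_fraction,
                 n_cornea = n_cornea, n_aqueous = n_aqueous,
                 n_lens = n_lens, n_vitreous = n_vitreous,
                 corneal_thickness = corneal_thickness,
                 lens_thickness = lens_thickness,
                 lens_front_radius = lens_front_radius,
                 lens_back_radius = lens_back_radius),
            class = "schematic_constants")
}

#' Build a four-surface paraxial eye model
#'
#' Assembles the personalised schematic eye: front and back corneal surfaces
#' at the measured front radius (back radius = `corneal_back_fraction` times
#' the front), lens front and back surfaces at the Gullstrand radii, with the
#' lens front apex placed at the measured anterior chamber depth and the
#' retina at the measured axial length.
#'
#' @param bio A [biometry()] object.
#' @param constants A [schematic_constants()] object.
#' @return An object of class `eye_model`: a list with `surfaces` (data frame
#'   of vertex position `z_mm`, signed `radius_mm`, media indices before and
#'   after) and `total_axial_length`.
#' @examples
#' eye <- build_four_surface_eye(biometry(23.30, 7.80, 3.12))
#' eye$surfaces
#' @export
build_four_surface_eye <- function(bio, constants = schematic_constants()) {
  stopifnot(inherits(bio, "biometry"), inherits(constants, "schematic_constants"))
  k <- constants
  r2 <- k$corneal_back_fraction * bio$corneal_radius
  z <- c(0, k$corneal_thickness, bio$acd, bio$acd + k$lens_thickness)
  if (bio$acd <= k$corneal_thickness)
    stop("invalid biometry: anterior chamber depth (", bio$acd,
         " mm) does not clear the corneal thickness")
  vitreous_gap <- bio$axial_length - z[4]
  if (vitreous_gap < 0)
    stop("invalid biometry: lens back surface lies behind the retina")
  surfaces <- data.frame(
    z_mm = z,
    radius_mm = c(bio$corneal_radius, r2, k$lens_front_radius,
                  k$lens_back_radius),
    n_before = c(1, k$n_cornea, k$n_aqueous, k$n_lens),
    n_after = c(k$n_cornea, k$n_aqueous, k$n_lens, k$n_vitreous))
  if (any(surfaces$radius_mm == 0) || any(!is.finite(surfaces$radius_mm)))
    stop("invalid biometry: non-positive or degenerate surface radius")
  structure(list(surfaces = surfaces,
                 total_axial_length = bio$axial_length),
            class = "eye_model")
}

#' Build a reduced-cornea (three-surface) variant of an eye model
#'
#' Replaces the two corneal surfaces by a single air-to-aqueous surface with
#' the same equivalent power, placed at the corneal apex. Used to check the
#' insensitivity of the nodal point to the corneal representation.
#'
#' @param bio A [biometry()] object.
#' @param constants A [schematic_constants()] object.
#' @return An `eye_model` with three surfaces.
#' @export
build_reduced_cornea_eye <- function(bio, constants = schematic_constants()) {
  stopifnot(inherits(bio, "biometry"))
  k <- constants
  r1 <- bio$corneal_radius
  r2 <- k$corneal_back_fraction * r1
  p1 <- (k$n_cornea - 1) / r1
  p2 <- (k$n_aqueous - k$n_cornea) / r2
  p_cornea <- p1 + p2 - (k$corneal_thickness / k$n_cornea) * p1 * p2
  r_eq <- (k$n_aqueous - 1) / p_cornea
  surfaces <- data.frame(
    z_mm = c(0, bio$acd, bio$acd + k$lens_thickness),
    radius_mm = c(r_eq, k$lens_front_radius, k$lens_back_radius),
    n_before = c(1, k$n_aqueous, k$n_lens),
    n_after = c(k$n_aqueous, k$n_lens, k$n_vitreous))
  structure(list(surfaces = surfaces,
                 total_axial_length = bio$axial_length),
            class = "eye_model")
}

#' Trace a paraxial ray through an eye model
#'
#' Propagates a paraxial ray (height `y`, real angle `u`, both measured in
#' object space at `z = z0`) through every refracting surface of the model
#' using the small-angle refraction equation n'u' = nu - yP.
#'
#' @param model An `eye_model`.
#' @param y Ray height at `z0` in mm.
#' @param u Ray angle in radians (real angle, not reduced).
#' @param z0 Starting axial position in mm (default 0, the corneal apex;
#'   negative values start the ray in air before the eye).
#' @return A list with `y`, `u` and `z` immediately after the last surface.
#' @export
trace_paraxial_ray <- function(model, y, u, z0 = 0) {
  stopifnot(inherits(model, "eye_model"))
  s <- model$surfaces
  z <- z0
  for (i in seq_len(nrow(s))) {
    y <- y + u * (s$z_mm[i] - z)
    z <- s$z_mm[i]
    p <- (s$n_after[i] - s$n_before[i]) / s$radius_mm[i]
    u <- (s$n_before[i] * u - y * p) / s$n_after[i]
  }
  list(y = y, u = u, z = z)
}

#' Cardinal points of an eye model
#'
#' Reduces the surface sequence to its Gaussian cardinal points by tracing a
#' ray parallel to the axis (and its reverse), yielding equivalent power,
#' focal points, principal points and both nodal points. All axial positions
#' are in mm from the corneal apex.
#'
#' @param model An `eye_model`.
#' @return A list with `power_mm` (equivalent power in 1/mm of air-equivalent
#'   focal length units), `efl_image_mm`, and positions `F`, `F_prime`, `H`,
#'   `H_prime`, `N`, `N_prime`.
#' @export
paraxial_cardinal_points <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  s <- model$surfaces
  n_obj <- s$n_before[1]
  n_img <- s$n_after[nrow(s)]
  fwd <- trace_paraxial_ray(model, y = 1, u = 0)
  if (abs(fwd$u) < 1e-12)
    stop("no-nodal-point: system has zero equivalent power")
  z_f2 <- fwd$z - fwd$y / fwd$u
  f2 <- -1 / fwd$u                      # image-space focal length (from H')
  z_h2 <- z_f2 - f2
  power <- n_img / f2
  # reverse trace: flip the system and trace parallel ray to find F, H
  rs <- s[rev(seq_len(nrow(s))), ]
  z_max <- max(s$z_mm)
  rev_model <- structure(list(surfaces = data.frame(
    z_mm = z_max - rs$z_mm,
    radius_mm = -rs$radius_mm,
    n_before = rs$n_after,
    n_after = rs$n_before),
    total_axial_length = model$total_axial_length), class = "eye_model")
  bwd <- trace_paraxial_ray(rev_model, y = 1, u = 0)
  z_f1_rev <- bwd$z - bwd$y / bwd$u
  f1 <- -1 / bwd$u                      # object-space focal length magnitude
  z_f1 <- z_max - z_f1_rev
  z_h1 <- z_max - (z_f1_rev - f1)
  shift <- (n_img - n_obj) / power
  list(power_mm = power,
       efl_image_mm = f2,
       F = z_f1, F_prime = z_f2,
       H = z_h1, H_prime = z_h2,
       N = z_h1 + shift, N_prime = z_h2 + shift)
}

#' Locate the secondary nodal point
#'
#' Distance from the corneal apex to the secondary nodal point N' of the eye
#' model. A paraxial ray aimed at the first nodal point at angle u leaves N'
#' toward the retina at the same angle, so N' anchors the conversion between
#' visual angle and retinal distance.
#'
#' @param model An `eye_model`.
#' @return Length in mm from the corneal apex (the quantity usually written
#'   AN').
#' @examples
#' locate_secondary_nodal_point(
#'   build_four_surface_eye(biometry(23.30, 7.80, 3.12)))
#' @export
locate_secondary_nodal_point <- function(model) {
  cp <- paraxial_cardinal_points(model)
  an2 <- cp$N_prime
  if (!is.finite(an2) || an2 <= 0 || an2 >= model$total_axial_length)
    stop("secondary nodal point (", round(an2, 3),
         " mm) falls outside the eye")
  an2
}

#' Retinal magnification factor from axial length and nodal point
#'
#' Microns of retina per degree of visual angle. Retinal image size relates
#' to visual angle through the distance from the secondary nodal point to
#' the retina: I = tan(1 deg) * (x - AN') per degree, with x the axial
#' length and AN' the secondary nodal point, both in mm.
#'
#' @param axial_length Axial length x in mm.
#' @param nodal_point_2 Secondary nodal point AN' in mm from the corneal apex.
#' @return RMF in microns per degree.
#' @examples
#' retinal_magnification_factor(23.30, 7.327)
#' @export
retinal_magnification_factor <- function(axial_length, nodal_point_2) {
  if (any(nodal_point_2 > axial_length))
    stop("nodal point cannot lie behind the retina")
  1000 * tan(pi / 180) * (axial_length - nodal_point_2)
}

#' Bennett's reduced-eye magnification approximation
#'
#' The classical reduced-eye shortcut RMF = 1000 * 0.01306 * (x - 1.82)
#' microns/degree, which assumes the eye's focal point coincides with the
#' retina. Compared with the four-surface ray trace it overestimates the RMF
#' of short (hyperopic) eyes and underestimates that of long (myopic) eyes.
#'
#' @param axial_length Axial length in mm; must exceed the 1.82 mm offset.
#' @param q Bennett proportionality constant in mm/deg.
#' @param offset Nodal-point offset in mm.
#' @return RMF in microns per degree.
#' @export
bennett_rmf <- function(axial_length, q = 0.01306, offset = 1.82) {
  if (any(axial_length < offset))
    stop("axial_length must be at least ", offset, " mm")
  1000 * q * (axial_length - offset)
}

#' Ray-traced RMF straight from biometry
#'
#' Convenience wrapper: build the four-surface model, locate the secondary
#' nodal point and evaluate the magnification factor.
#'
#' @param bio A [biometry()] object.
#' @param constants A [schematic_constants()] object.
#' @return A list with `an_prime_mm` and `rmf_um_per_deg`.
#' @examples
#' rmf_from_biometry(biometry(22.26, 7.37, 3.86))
#' @export
rmf_from_biometry <- function(bio, constants = schematic_constants()) {
  model <- build_four_surface_eye(bio, constants)
  an2 <- locate_secondary_nodal_point(model)
  list(an_prime_mm = an2,
       rmf_um_per_deg = retinal_magnification_factor(bio$axial_length, an2))
}

#' Add ray-traced RMF columns to a biometry table
#'
#' @param tab Data frame with columns `axial_length_mm`, `corneal_radius_mm`,
#'   `acd_mm` (the biometry CSV schema).
#' @param constants A [schematic_constants()] object.
#' @return `tab` with `an_prime_mm` and `rmf_um_per_deg` appended.
#' @export
add_rmf <- function(tab, constants = schematic_constants()) {
  need <- c("axial_length_mm", "corneal_radius_mm", "acd_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing biometry columns: ", paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(tab)), function(i) {
    rmf_from_biometry(biometry(tab$axial_length_mm[i],
                               tab$corneal_radius_mm[i],
                               tab$acd_mm[i]), constants)
  })
  tab$an_prime_mm <- vapply(res, `[[`, numeric(1), "an_prime_mm")
  tab$rmf_um_per_deg <- vapply(res, `[[`, numeric(1), "rmf_um_per_deg")
  tab
}
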