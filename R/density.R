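#' Convert between angular and linear cone density
#'
#' Angular density (cones/deg^2) and linear density (cones/mm^2) are related
#' through the retinal magnification factor: one degree of visual angle
#' subtends rmf/1000 mm of retina, so D_mm2 = D_deg2 / (rmf/1000)^2.
#'
#' @param d Density value(s).
#' @param rmf Retinal magnification factor in microns/degree.
#' @param direction `"ang_to_lin"` (deg^2 to mm^2) or `"lin_to_ang"`.
#' @return Converted density.
#' @examples
#' convert_density(15851, 278.81, "ang_to_lin")
#' @export
convert_density <- function(d, rmf, direction = c("ang_to_lin", "lin_to_ang")) {
  direction <- match.arg(direction)
  if (any(rmf <= 0)) stop("rmf must be positive")
  mm_per_deg <- rmf / 1000
  switch(direction,
         ang_to_lin = d / mm_per_deg^2,
         lin_to_ang = d * mm_per_deg^2)
}

# counts cones within radius (boundary inclusive) of each center row;
# centers: matrix (n x 2) in arcmin, radius scalar arcmin
.window_counts <- function(mosaic, centers, radius_arcmin) {
  pts <- mosaic_arcmin(mosaic)
  n_c <- nrow(centers)
  counts <- integer(n_c)
  if (!length(mosaic$x_px)) return(counts)
  r2 <- radius_arcmin^2
  # chunk the centers so the distance block stays modest in memory
  chunk <- max(1L, floor(4e6 / max(1L, nrow(pts))))
  for (s in seq(1L, n_c, by = chunk)) {
    e <- min(n_c, s + chunk - 1L)
    dx2 <- outer(centers[s:e, 1], pts[, 1], "-")^2
    dy2 <- outer(centers[s:e, 2], pts[, 2], "-")^2
    counts[s:e] <- as.integer(rowSums(dx2 + dy2 <= r2))
  }
  counts
}

.window_valid <- function(mosaic, centers, radius_arcmin) {
  ppa <- mosaic$pixels_per_arcmin
  w <- mosaic$width_px / ppa
  h <- mosaic$height_px / ppa
  centers[, 1] - radius_arcmin >= 0 & centers[, 1] + radius_arcmin <= w &
    centers[, 2] - radius_arcmin >= 0 & centers[, 2] + radius_arcmin <= h
}

#' Cone density in a circular sampling window
#'
#' Counts all cone centres falling on or within the boundary of a circular
#' window and divides by the window area, reporting angular density
#' (cones/deg^2) and, when the mosaic carries an RMF, linear density
#' (cones/mm^2). Windows extending beyond the analysed image region are
#' flagged invalid rather than truncated.
#'
#' @param mosaic A [cone_mosaic()].
#' @param center Window centre `c(x, y)` in arcmin.
#' @param diameter_arcmin Window diameter (default 10 arcmin).
#' @param unit_mode `"angular"`: the window is the stated angular circle and
#'   linear density follows by unit conversion. `"micron"`: the window is a
#'   circle of fixed physical diameter `diameter_arcmin/60 * rmf` microns at
#'   a nominal RMF of 300 um/deg (i.e. the same physical window for every
#'   eye), and angular density follows by conversion; requires an RMF.
#' @param nominal_rmf Nominal RMF used to fix the physical window size in
#'   `"micron"` mode.
#' @return A list with `n`, `d_ang`, `d_lin` (NA without an RMF), `valid`.
#' @examples
#' m <- cone_mosaic(c(47.4), c(47.4), rmf = 280)
#' window_density(m, center = c(5, 5))
#' @export
window_density <- function(mosaic, center, diameter_arcmin = 10,
                           unit_mode = c("angular", "micron"),
                           nominal_rmf = 300) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  unit_mode <- match.arg(unit_mode)
  if (diameter_arcmin <= 0) stop("diameter must be positive")
  center <- matrix(as.numeric(center), ncol = 2)
  radius <- diameter_arcmin / 2
  if (unit_mode == "micron") {
    if (is.null(mosaic$rmf)) stop("micron-window mode requires an RMF")
    # fixed physical diameter, expressed in this eye's arcmin
    diameter_um <- diameter_arcmin / 60 * nominal_rmf
    radius <- diameter_um / 2 / .um_per_arcmin(mosaic$rmf)
  }
  n <- .window_counts(mosaic, center, radius)
  area_deg2 <- pi * (radius / 60)^2
  d_ang <- n / area_deg2
  d_lin <- if (!is.null(mosaic$rmf))
    convert_density(d_ang, mosaic$rmf, "ang_to_lin") else NA_real_
  list(n = n, d_ang = d_ang, d_lin = d_lin,
       valid = .window_valid(mosaic, center, radius))
}

#' Continuous cone density map
#'
#' Evaluates the circular sampling window on a regular pixel grid across the
#' image, the sliding-window construction behind continuous foveal density
#' maps. Cells whose window crosses the image boundary are masked invalid.
#'
#' @param mosaic A [cone_mosaic()].
#' @param step_px Grid step in pixels (default 1; coarser steps trade
#'   resolution for speed).
#' @param diameter_arcmin Sampling window diameter.
#' @inheritParams window_density
#' @return An object of class `density_map`: grid coordinate vectors
#'   (`x_px`, `y_px`), matrices `d_ang`, `d_lin` (x by y), logical
#'   `valid`, plus the window and scale metadata.
#' @export
density_map <- function(mosaic, step_px = 1, diameter_arcmin = 10,
                        unit_mode = c("angular", "micron"),
                        nominal_rmf = 300) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  unit_mode <- match.arg(unit_mode)
  if (!is.numeric(step_px) || step_px <= 0) stop("step_px must be positive")
  gx <- seq(0, mosaic$width_px, by = step_px)
  gy <- seq(0, mosaic$height_px, by = step_px)
  ppa <- mosaic$pixels_per_arcmin
  centers <- cbind(rep(gx, times = length(gy)),
                   rep(gy, each = length(gx))) / ppa
  wd <- window_density(mosaic, centers, diameter_arcmin,
                       unit_mode = unit_mode, nominal_rmf = nominal_rmf)
  dim_ang <- matrix(wd$d_ang, nrow = length(gx))
  dim_lin <- matrix(wd$d_lin, nrow = length(gx))
  valid <- matrix(wd$valid, nrow = length(gx))
  structure(list(x_px = gx, y_px = gy,
                 d_ang = dim_ang, d_lin = dim_lin, valid = valid,
                 step_px = step_px, diameter_arcmin = diameter_arcmin,
                 pixels_per_arcmin = ppa, rmf = mosaic$rmf,
                 unit_mode = unit_mode),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map>", length(x$x_px), "x", length(x$y_px),
      "cells, step", x$step_px, "px, window", x$diameter_arcmin, "arcmin,",
      sum(x$valid), "valid cells\n")
  invisible(x)
}

#' Location and value of peak cone density
#'
#' Maximum of the density map over valid cells. Exact ties are resolved by
#' the centroid of the maximal set (so a constant map peaks at the centre of
#' its valid region).
#'
#' @param map A [density_map()].
#' @return List with `location_arcmin`, `location_px`, `d_ang`, `d_lin`.
#' @export
find_peak <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (!any(map$valid)) stop("no valid cells in density map")
  v <- map$d_ang
  v[!map$valid] <- -Inf
  mx <- max(v)
  idx <- which(v == mx, arr.ind = TRUE)
  loc_px <- c(mean(map$x_px[idx[, 1]]), mean(map$y_px[idx[, 2]]))
  d_lin <- if (all(is.na(map$d_lin))) NA_real_ else {
    # density at the (possibly tied) peak value, converted consistently
    map$d_lin[idx[1, 1], idx[1, 2]]
  }
  list(location_arcmin = loc_px / map$pixels_per_arcmin,
       location_px = loc_px,
       d_ang = mx, d_lin = d_lin)
}

#' Radial (annular) density profile
#'
#' Mean cone density in concentric annuli of equal width around a centre,
#' usually the point of peak density. Annulus membership is inner-exclusive
#' and outer-inclusive, with the innermost disk including its centre.
#' Annuli extending beyond the analysed region are flagged.
#'
#' @param mosaic A [cone_mosaic()].
#' @param center Centre `c(x, y)` in arcmin.
#' @param width Annulus width: in arcmin when `unit = "arcmin"` (default 5),
#'   in microns when `unit = "um"` (default 25).
#' @param unit `"arcmin"` or `"um"`.
#' @param max_eccentricity Outer limit of the profile, in `unit`.
#' @return A data frame with inner/outer radii (in `unit`), cone counts,
#'   densities in both unit systems and a validity flag; class
#'   `eccentricity_profile`.
#' @export
annular_profile <- function(mosaic, center, width = NULL,
                            unit = c("arcmin", "um"),
                            max_eccentricity = NULL) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  unit <- match.arg(unit)
  if (is.null(width)) width <- if (unit == "arcmin") 5 else 25
  if (width <= 0) stop("annulus width must be positive")
  if (unit == "um" && is.null(mosaic$rmf))
    stop("micron-unit profiles require an RMF")
  scale_arcmin <- if (unit == "arcmin") 1 else 1 / .um_per_arcmin(mosaic$rmf)
  if (is.null(max_eccentricity)) {
    half_span <- min(mosaic$width_px, mosaic$height_px) /
      mosaic$pixels_per_arcmin / 2
    max_eccentricity <- floor(half_span / (width * scale_arcmin)) * width
  }
  edges <- seq(0, max_eccentricity, by = width)
  if (length(edges) < 2) stop("max_eccentricity smaller than one annulus")
  pts <- mosaic_arcmin(mosaic)
  r <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  r_unit <- r / scale_arcmin
  inner <- edges[-length(edges)]
  outer <- edges[-1]
  n <- vapply(seq_along(inner), function(i) {
    if (inner[i] == 0) sum(r_unit <= outer[i])
    else sum(r_unit > inner[i] & r_unit <= outer[i])
  }, integer(1))
  area_unit2 <- pi * (outer^2 - inner^2)
  if (unit == "arcmin") {
    d_ang <- n / (area_unit2 / 3600)
    d_lin <- if (!is.null(mosaic$rmf))
      convert_density(d_ang, mosaic$rmf, "ang_to_lin") else NA_real_
  } else {
    d_lin <- n / (area_unit2 / 1e6)        # um^2 -> mm^2
    d_ang <- convert_density(d_lin, mosaic$rmf, "lin_to_ang")
  }
  # annulus valid iff its outer circle lies inside the image region
  outer_arcmin <- outer * scale_arcmin
  valid <- .window_valid(mosaic, matrix(center, ncol = 2)[rep(1, length(outer)), , drop = FALSE],
                         outer_arcmin)
  structure(data.frame(inner = inner, outer = outer, n = n,
                       d_ang = d_ang, d_lin = d_lin, valid = valid),
            unit = unit, center = center, class = c("eccentricity_profile", "data.frame"))
}

#' Density profile along a cardinal meridian
#'
#' Sliding-window density evaluated at regular steps along the horizontal or
#' vertical line through a centre, used to compare falloff steepness across
#' meridians.
#'
#' @param mosaic A [cone_mosaic()].
#' @param center Centre `c(x, y)` in arcmin.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param step_arcmin Sample spacing along the meridian; `0` collapses the
#'   profile to the single window at the centre.
#' @param max_eccentricity Largest |offset| sampled, arcmin.
#' @param diameter_arcmin Sampling window diameter.
#' @return Data frame with signed `position` (arcmin from the centre),
#'   densities in both unit systems and validity flags.
#' @export
directional_profile <- function(mosaic, center,
                                axis = c("horizontal", "vertical"),
                                step_arcmin = 1, max_eccentricity = 30,
                                diameter_arcmin = 10) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  axis <- match.arg(axis)
  if (step_arcmin < 0) stop("step must be non-negative")
  pos <- if (step_arcmin == 0) 0 else
    seq(-max_eccentricity, max_eccentricity, by = step_arcmin)
  centers <- if (axis == "horizontal")
    cbind(center[1] + pos, center[2]) else cbind(center[1], center[2] + pos)
  wd <- window_density(mosaic, centers, diameter_arcmin)
  data.frame(position = pos, n = wd$n, d_ang = wd$d_ang, d_lin = wd$d_lin,
             valid = wd$valid)
}
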