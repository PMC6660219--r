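#' Nyquist sampling limit of a hexagonal cone mosaic
#'
#' Highest spatial frequency a hexagonally packed mosaic of angular density
#' D (cones/deg^2) can represent without aliasing, set by the row-to-row
#' spacing of the lattice: N = (1/2) * sqrt(2 D / sqrt(3)) cycles/degree.
#'
#' @param d_ang Angular cone density, cones/deg^2 (vectorised).
#' @return Nyquist limit in cycles/degree.
#' @examples
#' nyquist_limit(8813)   # ~50.4 cyc/deg
#' @export
nyquist_limit <- function(d_ang) {
  if (any(d_ang < 0)) stop("density must be non-negative")
  0.5 * sqrt(2 * d_ang / sqrt(3))
}

#' Cone centre-to-centre spacing from the Nyquist limit
#'
#' Inverts the hexagonal-packing relation: s = 60 / (sqrt(3) * N) arcmin,
#' so that a lattice with spacing s has density 2 / (sqrt(3) s^2).
#'
#' @param n_cpd Nyquist limit in cycles/degree (vectorised, positive).
#' @return Centre-to-centre spacing in arcmin.
#' @examples
#' cone_spacing(nyquist_limit(8813))   # ~0.69 arcmin
#' @export
cone_spacing <- function(n_cpd) {
  if (any(n_cpd <= 0)) stop("Nyquist limit must be positive")
  60 / (sqrt(3) * n_cpd)
}

#' Angular density of an ideal hexagonal lattice
#'
#' Closed form D = 2 / (sqrt(3) * (s/60)^2) cones/deg^2 for centre-to-centre
#' spacing s in arcmin; the exact inverse of
#' `cone_spacing(nyquist_limit(D))`.
#'
#' @param spacing_arcmin Centre-to-centre spacing in arcmin.
#' @return Angular density in cones/deg^2.
#' @export
hex_density <- function(spacing_arcmin) {
  if (any(spacing_arcmin <= 0)) stop("spacing must be positive")
  2 / (sqrt(3) * (spacing_arcmin / 60)^2)
}

#' Approximate Snellen equivalent of a sampling limit
#'
#' Converts a resolution limit in cycles/degree into the denominator of a
#' 20/x Snellen fraction via the primary spatial frequency of a letter E
#' (30 cyc/deg at 20/20): x = 20 * 30 / N. Approximate by construction.
#'
#' @param n_cpd Nyquist limit in cycles/degree.
#' @return Snellen denominator (20/x).
#' @export
snellen_equivalent <- function(n_cpd) {
  if (any(n_cpd <= 0)) stop("Nyquist limit must be positive")
  20 * 30 / n_cpd
}

#' Append sampling-limit columns to a cohort table
#'
#' @param cohort Data frame with an angular-density column.
#' @param density_col Name of the angular-density column (cones/deg^2).
#' @param prefix Prefix for the new columns.
#' @return `cohort` with `<prefix>nyquist_cpd` and `<prefix>spacing_arcmin`.
#' @export
add_sampling_columns <- function(cohort, density_col = "peak_density_deg2",
                                 prefix = "") {
  if (!density_col %in% names(cohort))
    stop("no such column: ", density_col)
  n <- nyquist_limit(cohort[[density_col]])
  cohort[[paste0(prefix, "nyquist_cpd")]] <- n
  cohort[[paste0(prefix, "spacing_arcmin")]] <- cone_spacing(n)
  cohort
}
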