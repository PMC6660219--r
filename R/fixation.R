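#' A fixation trace
#'
#' Per-frame positions of a fixated stimulus on the retina, in the same
#' arcmin coordinate frame as the cone mosaic.
#'
#' @param x_arcmin,y_arcmin Numeric vectors of stimulus positions.
#' @param eye_id Optional identifier.
#' @return Object of class `fixation_trace`.
#' @export
fixation_trace <- function(x_arcmin, y_arcmin, eye_id = NULL) {
  stopifnot(length(x_arcmin) == length(y_arcmin))
  if (!length(x_arcmin)) stop("empty fixation trace")
  if (any(!is.finite(x_arcmin)) || any(!is.finite(y_arcmin)))
    stop("fixation trace contains non-finite coordinates")
  structure(list(x = as.numeric(x_arcmin), y = as.numeric(y_arcmin),
                 eye_id = eye_id),
            class = "fixation_trace")
}

#' Fit the fixation ellipse and bivariate contour ellipse area
#'
#' Estimates the preferred retinal locus (PRL) as the centroid of the
#' fixation scatter and quantifies fixation stability as the bivariate
#' contour ellipse area (BCEA): the area of the ellipse containing a stated
#' fraction of fixation positions (68% by default).
#'
#' Two readings of "the ellipse encompassing 68% of the points" are offered.
#' The default, `method = "covariance"`, scales the sample-covariance
#' ellipse by the chi-square quantile with 2 df at `coverage` (k = 2.279 at
#' 0.68), giving BCEA = pi * k * sqrt(det(S)). `method = "empirical"`
#' instead dilates the covariance ellipse until it contains exactly
#' `ceiling(coverage * n)` points.
#'
#' @param trace A [fixation_trace()].
#' @param coverage Ellipse coverage fraction, default 0.68.
#' @param method `"covariance"` (parametric) or `"empirical"` (containment).
#' @param rmf Optional RMF (microns/degree) to also report the BCEA in
#'   square microns.
#' @return Object of class `prl_estimate`: centroid, covariance, semi-axes,
#'   orientation (radians, major axis vs +x), `k`, `bcea_ang` (arcmin^2) and
#'   `bcea_lin` (um^2, NA without `rmf`).
#' @examples
#' set.seed(1)
#' tr <- fixation_trace(rnorm(500), rnorm(500))
#' fit_fixation_ellipse(tr)$bcea_ang
#' @export
fit_fixation_ellipse <- function(trace, coverage = 0.68,
                                 method = c("covariance", "empirical"),
                                 rmf = NULL) {
  stopifnot(inherits(trace, "fixation_trace"))
  method <- match.arg(method)
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  n <- length(trace$x)
  centroid <- c(mean(trace$x), mean(trace$y))
  if (n < 3) stop("ellipse fitting needs at least 3 fixation points")
  S <- stats::cov(cbind(trace$x, trace$y))
  detS <- det(S)
  k <- stats::qchisq(coverage, df = 2)
  if (detS <= .Machine$double.eps) {
    warning("degenerate (collinear or constant) fixation trace; BCEA = 0")
    detS <- max(detS, 0)
    k_use <- k
  } else if (method == "empirical") {
    d2 <- stats::mahalanobis(cbind(trace$x, trace$y), centroid, S)
    m <- min(n, ceiling(coverage * n))
    k_use <- sort(d2)[m]
  } else {
    k_use <- k
  }
  eg <- eigen(S, symmetric = TRUE)
  semi_axes <- sqrt(pmax(eg$values, 0) * k_use)
  orientation <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  bcea_ang <- pi * k_use * sqrt(detS)
  bcea_lin <- if (!is.null(rmf)) bcea_ang * (.um_per_arcmin(rmf))^2 else NA_real_
  structure(list(centroid = centroid, covariance = S,
                 semi_axes = semi_axes, orientation = orientation,
                 coverage = coverage, k = k_use, method = method, n = n,
                 bcea_ang = bcea_ang, bcea_lin = bcea_lin, rmf = rmf),
            class = "prl_estimate")
}

#' @export
print.prl_estimate <- function(x, ...) {
  cat("<prl_estimate> centroid (", round(x$centroid[1], 2), ",",
      round(x$centroid[2], 2), ") arcmin; BCEA",
      round(x$bcea_ang, 2), "arcmin^2",
      if (!is.na(x$bcea_lin)) paste0("(", round(x$bcea_lin, 1), " um^2)"),
      "at", x$coverage, "coverage,", x$method, "method\n")
  invisible(x)
}

#' Relate the PRL to the density peak
#'
#' Euclidean displacement between the fixation centroid (PRL) and the point
#' of peak cone density, in arcmin and microns, plus the cone density inside
#' the sampling window centred on the PRL when a mosaic is supplied.
#'
#' @param prl A `prl_estimate`.
#' @param peak_location Peak-density location `c(x, y)` in arcmin, in the
#'   same frame as the fixation trace.
#' @param rmf RMF in microns/degree for the linear displacement.
#' @param mosaic Optional [cone_mosaic()] for density at the PRL.
#' @param diameter_arcmin Sampling window for the PRL density.
#' @return List with `displacement_arcmin`, `displacement_um`, and (with a
#'   mosaic) `prl_d_ang`, `prl_d_lin`.
#' @export
prl_metrics <- function(prl, peak_location, rmf, mosaic = NULL,
                        diameter_arcmin = 10) {
  stopifnot(inherits(prl, "prl_estimate"))
  if (length(peak_location) != 2 || any(!is.finite(peak_location)))
    stop("peak_location must be a finite (x, y) pair in the trace frame")
  d_arcmin <- sqrt(sum((prl$centroid - peak_location)^2))
  out <- list(displacement_arcmin = d_arcmin,
              displacement_um = d_arcmin * .um_per_arcmin(rmf))
  if (!is.null(mosaic)) {
    wd <- window_density(mosaic, prl$centroid, diameter_arcmin)
    out$prl_d_ang <- wd$d_ang
    out$prl_d_lin <- wd$d_lin
    out$prl_window_valid <- wd$valid
  }
  out
}
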