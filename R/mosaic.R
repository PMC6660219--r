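#' A labelled cone mosaic
#'
#' Container for cone centre coordinates from a fundus image, together with
#' the angular scale of the image and (optionally) the eye's retinal
#' magnification factor, which enables linear-unit densities.
#'
#' Coordinates are 0-based image pixels, x to the right and y down. The
#' analysed region is the rectangle `[0, width_px] x [0, height_px]`;
#' sampling windows are only considered valid when they lie fully inside it.
#'
#' @param x_px,y_px Numeric vectors of cone centre coordinates in pixels.
#' @param pixels_per_arcmin Image scale (default 9.48 px/arcmin).
#' @param rmf Retinal magnification factor in microns/degree, or `NULL` if
#'   only angular-unit analyses are wanted.
#' @param eye_id Optional identifier carried through reports.
#' @param width_px,height_px Image extent in pixels; defaults to the ceiling
#'   of the largest coordinate.
#' @return An object of class `cone_mosaic`.
#' @export
cone_mosaic <- function(x_px, y_px, pixels_per_arcmin = 9.48, rmf = NULL,
                        eye_id = NULL, width_px = NULL, height_px = NULL) {
  stopifnot(length(x_px) == length(y_px))
  if (length(x_px) && (any(!is.finite(x_px)) || any(!is.finite(y_px))))
    stop("cone coordinates must be finite")
  if (!is.numeric(pixels_per_arcmin) || pixels_per_arcmin <= 0)
    stop("pixels_per_arcmin must be positive")
  if (is.null(width_px)) width_px <- if (length(x_px)) ceiling(max(x_px)) else 0
  if (is.null(height_px)) height_px <- if (length(y_px)) ceiling(max(y_px)) else 0
  if (length(x_px) && (any(x_px < 0 | x_px > width_px) ||
                       any(y_px < 0 | y_px > height_px)))
    stop("cone coordinates fall outside the declared image bounds")
  m <- structure(list(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                      pixels_per_arcmin = pixels_per_arcmin,
                      rmf = rmf, eye_id = eye_id,
                      width_px = width_px, height_px = height_px),
                 class = "cone_mosaic")
  dup <- .near_duplicates(m$x_px / pixels_per_arcmin,
                          m$y_px / pixels_per_arcmin, tol = 0.05)
  if (dup > 0)
    stop(dup, " cone pair(s) closer than 0.05 arcmin: duplicate labels?")
  m
}

# count point pairs closer than tol using a cell hash (avoids O(n^2) dist)
.near_duplicates <- function(x, y, tol) {
  n <- length(x)
  if (n < 2) return(0L)
  h <- tol
  ix <- floor(x / h); iy <- floor(y / h)
  key <- paste(ix, iy)
  cells <- split(seq_len(n), key)
  count <- 0L
  for (idx in cells) {
    if (length(idx) < 2) next
    d <- stats::dist(cbind(x[idx], y[idx]))
    count <- count + sum(d < tol)
  }
  # neighbouring cells: shift-and-rehash in the four forward directions
  for (sh in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    key2 <- paste(ix + sh[1], iy + sh[2])
    common <- intersect(unique(key), unique(key2))
    for (k in common) {
      a <- which(key == k); b <- which(key2 == k)
      d2 <- outer(x[a], x[b], "-")^2 + outer(y[a], y[b], "-")^2
      count <- count + sum(d2 < tol^2)
    }
  }
  count
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat("<cone_mosaic>", length(x$x_px), "cones,",
      x$width_px, "x", x$height_px, "px at",
      x$pixels_per_arcmin, "px/arcmin")
  if (!is.null(x$rmf)) cat(", rmf", round(x$rmf, 2), "um/deg")
  if (!is.null(x$eye_id)) cat(", eye", x$eye_id)
  cat("\n")
  invisible(x)
}

#' Cone coordinates in arcminutes
#'
#' @param mosaic A [cone_mosaic()].
#' @return Two-column matrix of coordinates in arcmin (same origin as the
#'   pixel frame).
#' @export
mosaic_arcmin <- function(mosaic) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  cbind(x = mosaic$x_px, y = mosaic$y_px) / mosaic$pixels_per_arcmin
}

# microns per arcmin for a mosaic with a known RMF
.um_per_arcmin <- function(rmf) rmf / 60
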