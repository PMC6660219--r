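#' Analysis configuration
#'
#' Collects every tunable of the per-eye pipeline. Defaults are the
#' conventional choices for foveal AOSLO analysis: 10-arcmin circular
#' sampling window, 5-arcmin and 25-micron annuli, 68% BCEA coverage.
#'
#' @param window_diameter_arcmin Sampling window diameter.
#' @param grid_step_px Density-map grid step in pixels.
#' @param annulus_arcmin Angular annulus width.
#' @param annulus_um Linear annulus width.
#' @param bcea_coverage BCEA coverage fraction.
#' @param unit_mode `"angular"` or `"micron"` sampling-window definition.
#' @param constants [schematic_constants()] for the eye model.
#' @param seed Integer seed recorded in outputs.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(window_diameter_arcmin = 10,
                            grid_step_px = 1,
                            annulus_arcmin = 5,
                            annulus_um = 25,
                            bcea_coverage = 0.68,
                            unit_mode = c("angular", "micron"),
                            constants = schematic_constants(),
                            seed = 1) {
  unit_mode <- match.arg(unit_mode)
  stopifnot(window_diameter_arcmin > 0, grid_step_px > 0,
            annulus_arcmin > 0, annulus_um > 0,
            bcea_coverage > 0, bcea_coverage < 1)
  structure(list(window_diameter_arcmin = window_diameter_arcmin,
                 grid_step_px = grid_step_px,
                 annulus_arcmin = annulus_arcmin,
                 annulus_um = annulus_um,
                 bcea_coverage = bcea_coverage,
                 unit_mode = unit_mode,
                 constants = constants,
                 seed = seed),
            class = "analysis_config")
}

# short stable hash of a config (records provenance in reports)
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

.read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(label, " CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (cl in required) {
    v <- tab[[cl]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(label, " CSV ", path, ": non-numeric value in column '", cl,
             "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      tab[[cl]] <- num
    }
  }
  tab
}

#' Read labelled cone coordinates
#'
#' Expects a CSV with header `x_px,y_px`; scale and magnification metadata
#' are supplied as arguments (they normally live in a sidecar config).
#'
#' @param path CSV path.
#' @param pixels_per_arcmin,rmf,eye_id,width_px,height_px Passed to
#'   [cone_mosaic()].
#' @return A [cone_mosaic()].
#' @export
read_cone_csv <- function(path, pixels_per_arcmin = 9.48, rmf = NULL,
                          eye_id = NULL, width_px = NULL, height_px = NULL) {
  tab <- .read_checked_csv(path, c("x_px", "y_px"), "cone coordinate")
  cone_mosaic(tab$x_px, tab$y_px, pixels_per_arcmin = pixels_per_arcmin,
              rmf = rmf, eye_id = eye_id, width_px = width_px,
              height_px = height_px)
}

#' Write cone coordinates
#'
#' @param mosaic A [cone_mosaic()].
#' @param path Output CSV path.
#' @export
write_cone_csv <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  utils::write.csv(data.frame(x_px = mosaic$x_px, y_px = mosaic$y_px),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a fixation trace
#'
#' Expects a CSV with header `frame,x_arcmin,y_arcmin`.
#'
#' @param path CSV path.
#' @param eye_id Optional identifier.
#' @return A [fixation_trace()].
#' @export
read_trace_csv <- function(path, eye_id = NULL) {
  tab <- .read_checked_csv(path, c("frame", "x_arcmin", "y_arcmin"),
                           "fixation trace")
  fixation_trace(tab$x_arcmin, tab$y_arcmin, eye_id = eye_id)
}

#' Write a fixation trace
#'
#' @param trace A [fixation_trace()].
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fixation_trace"))
  utils::write.csv(data.frame(frame = seq_along(trace$x),
                              x_arcmin = trace$x, y_arcmin = trace$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a per-eye biometry table
#'
#' Expects the schema `subject,eye,axial_length_mm,corneal_radius_mm,acd_mm`
#' (extra columns pass through). Duplicate (subject, eye) pairs are an
#' error.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_biometry_csv <- function(path) {
  tab <- .read_checked_csv(path, c("axial_length_mm", "corneal_radius_mm",
                                   "acd_mm"), "biometry")
  if (!all(c("subject", "eye") %in% names(tab)))
    stop("biometry CSV ", path, " is missing column(s): subject, eye")
  key <- paste(tab$subject, tab$eye)
  if (anyDuplicated(key))
    stop("duplicate (subject, eye) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  tab
}

#' Read / write a cohort table
#'
#' The cohort schema is that of the packaged reference fixture: per-eye
#' biometry, RMF, peak and PRL densities in both unit systems, and PRL
#' displacement.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  tab <- .read_checked_csv(path, c(
    "axial_length_mm", "rmf_um_per_deg",
    "peak_density_deg2", "peak_density_mm2",
    "prl_dist_arcmin", "prl_dist_um",
    "prl_density_deg2", "prl_density_mm2"), "cohort")
  if (!all(c("subject", "eye") %in% names(tab)))
    stop("cohort CSV ", path, " is missing column(s): subject, eye")
  key <- paste(tab$subject, tab$eye)
  if (anyDuplicated(key))
    stop("duplicate (subject, eye) pair(s) in ", path)
  tab
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Packaged reference cohort (28 eyes of 16 subjects)
#'
#' The per-eye biometry, ray-traced RMF, peak and PRL cone densities and
#' PRL displacements of the 28-eye reference cohort, as published. Ships as
#' a plain CSV fixture; all cohort-level analyses and validation tests run
#' against it.
#'
#' @return Data frame with 28 rows.
#' @examples
#' nrow(table2_cohort())
#' @export
table2_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv",
                      package = "foveatopo", mustWork = TRUE)
  read_cohort_csv(path)
}

#' Write a density map as a CSV grid
#'
#' Long-format CSV with one row per grid cell (`x_px,y_px,d_ang,d_lin,valid`),
#' losslessly re-readable with [read_density_csv()].
#'
#' @param map A [density_map()].
#' @param path Output CSV path.
#' @export
write_density_csv <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  grid <- expand.grid(x_px = map$x_px, y_px = map$y_px)
  grid$d_ang <- as.vector(map$d_ang)
  grid$d_lin <- as.vector(map$d_lin)
  grid$valid <- as.vector(map$valid)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  tab <- .read_checked_csv(path, c("x_px", "y_px", "d_ang"), "density map")
  tab
}

#' Run the whole per-eye pipeline over a set of eyes
#'
#' For each eye: ray-traced RMF from biometry, density map and peak, radial
#' profile, PRL/BCEA from the fixation trace, PRL-to-peak displacement and
#' sampling limits; then cohort-level regressions and summaries over the
#' per-eye reports. Any stage failure aborts that eye with a recorded
#' reason, not the whole run.
#'
#' @param eyes List of per-eye inputs; each element is a list with
#'   `biometry` (a [biometry()]), `mosaic` (a [cone_mosaic()]), `trace`
#'   (a [fixation_trace()], optional) and `id`.
#' @param config An [analysis_config()].
#' @return List with `per_eye` (data frame in the cohort schema, plus
#'   Nyquist/spacing columns), `regressions` (when >= 3 eyes succeed),
#'   `failures` (named reasons), `config_hash` and `seed`.
#' @export
run_pipeline <- function(eyes, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  failures <- list()
  for (i in seq_along(eyes)) {
    e <- eyes[[i]]
    id <- if (!is.null(e$id)) e$id else paste0("eye", i)
    res <- tryCatch({
      r <- rmf_from_biometry(e$biometry, config$constants)
      mosaic <- e$mosaic
      mosaic$rmf <- r$rmf_um_per_deg
      map <- density_map(mosaic, step_px = config$grid_step_px,
                         diameter_arcmin = config$window_diameter_arcmin,
                         unit_mode = config$unit_mode)
      peak <- find_peak(map)
      if (!is.null(e$trace)) {
        prl <- fit_fixation_ellipse(e$trace, coverage = config$bcea_coverage,
                                    rmf = r$rmf_um_per_deg)
        pm <- prl_metrics(prl, peak$location_arcmin, r$rmf_um_per_deg,
                          mosaic = mosaic,
                          diameter_arcmin = config$window_diameter_arcmin)
        prl_cols <- data.frame(
          prl_dist_arcmin = pm$displacement_arcmin,
          prl_dist_um = pm$displacement_um,
          prl_density_deg2 = pm$prl_d_ang,
          prl_density_mm2 = pm$prl_d_lin,
          bcea_arcmin2 = prl$bcea_ang,
          bcea_um2 = prl$bcea_lin)
      } else {
        prl_cols <- data.frame(prl_dist_arcmin = NA_real_,
                               prl_dist_um = NA_real_,
                               prl_density_deg2 = NA_real_,
                               prl_density_mm2 = NA_real_,
                               bcea_arcmin2 = NA_real_, bcea_um2 = NA_real_)
      }
      cbind(data.frame(subject = id, eye = "",
                       axial_length_mm = e$biometry$axial_length,
                       corneal_radius_mm = e$biometry$corneal_radius,
                       acd_mm = e$biometry$acd,
                       an_prime_mm = r$an_prime_mm,
                       rmf_um_per_deg = r$rmf_um_per_deg,
                       peak_density_deg2 = peak$d_ang,
                       peak_density_mm2 = peak$d_lin,
                       peak_x_arcmin = peak$location_arcmin[1],
                       peak_y_arcmin = peak$location_arcmin[2]),
            prl_cols)
    }, error = function(err) err)
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  per_eye <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(per_eye)) {
    per_eye <- add_sampling_columns(per_eye, "peak_density_deg2", "peak_")
    row.names(per_eye) <- NULL
  }
  regs <- if (!is.null(per_eye) && nrow(per_eye) >= 3 &&
              !anyNA(per_eye$prl_density_deg2)) {
    cohort_regressions(per_eye)
  } else NULL
  list(per_eye = per_eye, regressions = regs, failures = failures,
       config_hash = config_hash(config), seed = config$seed)
}
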