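#' Four-channel acceptor-photobleaching acquisition
#'
#' Container for the four registered intensity images of one cell: donor
#' (eCFP) and acceptor (eYFP) channels, each before and after acceptor
#' bleaching. Images are numeric matrices of identical shape holding photon
#' counts; they stay floating point in memory and are quantized to 16-bit
#' only when written to TIFF.
#'
#' @param donor_pre,donor_post,acceptor_pre,acceptor_post nonnegative
#'   numeric matrices, all the same shape
#' @param pixel_size_um physical pixel size in micrometers (> 0)
#' @return an object of class `fret_acquisition`
#' @export
fret_acquisition <- function(donor_pre, donor_post, acceptor_pre,
                             acceptor_post, pixel_size_um) {
  dims <- lapply(list(donor_pre, donor_post, acceptor_pre, acceptor_post), dim)
  if (length(unique(dims)) != 1L)
    stop("all four channel images must have identical dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  for (img in list(donor_pre, donor_post, acceptor_pre, acceptor_post))
    if (any(img < 0)) stop("channel images must be nonnegative")
  structure(list(donor_pre = donor_pre, donor_post = donor_post,
                 acceptor_pre = acceptor_pre, acceptor_post = acceptor_post,
                 pixel_size_um = pixel_size_um),
            class = "fret_acquisition")
}

#' @export
print.fret_acquisition <- function(x, ...) {
  d <- dim(x$donor_pre)
  cat(sprintf("<fret_acquisition> %d x %d px, %.3g um/px\n",
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' ROI panel for one acquisition
#'
#' The bleached region, up to six measurement ROIs inside it, and one
#' unbleached reference ROI whose edge-to-edge distance from the bleached
#' region must be at least `min_dist_um` (3 um by default, the acquisition
#' protocol's rule). Violations are errors at construction, never silent.
#'
#' @param bleach_region logical mask of the bleached area
#' @param measurement_rois named list of at most six nonempty logical masks,
#'   each a subset of `bleach_region`
#' @param unbleached_roi logical mask of the unbleached reference region
#' @param pixel_size_um pixel size in micrometers
#' @param min_dist_um minimum edge-to-edge distance (um) between the
#'   unbleached ROI and the bleached region
#' @param shapes optional named list of `fretab_shape` objects (used to
#'   serialize the panel as a JSON sidecar); names `bleach`, `unbleached`,
#'   and one per measurement ROI
#' @return an object of class `roi_panel`
#' @export
roi_panel <- function(bleach_region, measurement_rois, unbleached_roi,
                      pixel_size_um, min_dist_um = 3, shapes = NULL) {
  stopifnot(is.matrix(bleach_region), is.logical(bleach_region))
  if (!is.list(measurement_rois) || length(measurement_rois) < 1L)
    stop("at least one measurement ROI is required")
  if (length(measurement_rois) > 6L)
    stop("at most six measurement ROIs are supported")
  if (is.null(names(measurement_rois)))
    names(measurement_rois) <- paste0("roi", seq_along(measurement_rois))
  for (nm in names(measurement_rois)) {
    m <- measurement_rois[[nm]]
    if (!any(m)) stop("measurement ROI '", nm, "' is empty")
    if (!identical(dim(m), dim(bleach_region)))
      stop("measurement ROI '", nm, "' has mismatched dimensions")
    if (!mask_subset(m, bleach_region))
      stop("measurement ROI '", nm, "' is not inside the bleached region")
  }
  if (!any(unbleached_roi)) stop("unbleached ROI is empty")
  d <- mask_distance_um(unbleached_roi, bleach_region, pixel_size_um)
  if (d < min_dist_um)
    stop(sprintf(
      "unbleached ROI is %.2f um from the bleached region (minimum %g um)",
      d, min_dist_um))
  structure(list(bleach_region = bleach_region,
                 measurement_rois = measurement_rois,
                 unbleached_roi = unbleached_roi,
                 pixel_size_um = pixel_size_um,
                 min_dist_um = min_dist_um,
                 shapes = shapes),
            class = "roi_panel")
}

#' @export
print.roi_panel <- function(x, ...) {
  cat(sprintf(
    "<roi_panel> %d measurement ROI(s), unbleached ROI at >= %g um\n",
    length(x$measurement_rois), x$min_dist_um))
  invisible(x)
}
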