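#' TIFF and ROI-sidecar input/output
#'
#' Acquisitions are written as one 16-bit grayscale TIFF per channel and
#' timepoint plus one JSON sidecar holding the pixel size, the ROI shape
#' definitions (named circles/rectangles with 0-based pixel coordinates)
#' and, for synthetic data, the generating ground truth. Counts are
#' clipped to `[0, 65535]` and rounded at write time; reading restores
#' integer counts exactly.
#'
#' @name fret_io
NULL

channel_files <- c("donor_pre", "donor_post", "acceptor_pre", "acceptor_post")

quantize16 <- function(img) pmin(pmax(round(img), 0), 65535) / 65535

shape_to_json <- function(shape) {
  if (shape$type == "circle")
    list(type = "circle", x = shape$x - 1, y = shape$y - 1, r = shape$r)
  else
    list(type = "rect", xmin = shape$xmin - 1, xmax = shape$xmax - 1,
         ymin = shape$ymin - 1, ymax = shape$ymax - 1)
}

shape_from_json <- function(s) {
  if (s$type == "circle") shape_circle(s$x + 1, s$y + 1, s$r)
  else shape_rect(s$xmin + 1, s$xmax + 1, s$ymin + 1, s$ymax + 1)
}

#' Write ROI shape definitions as JSON
#'
#' @param shapes named list of `fretab_shape` objects
#' @param pixel_size_um pixel size recorded in the sidecar
#' @param file output path
#' @param extra optional named list merged into the JSON object (e.g.
#'   ground truth)
#' @export
write_roi_json <- function(shapes, pixel_size_um, file, extra = NULL) {
  obj <- c(list(pixel_size_um = pixel_size_um,
                rois = lapply(shapes, shape_to_json)), extra)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname fret_io
#' @param sim a simulated cell: list with `acquisition`, `panel`, and
#'   optionally `ground_truth` (as returned by
#'   [simulate_fret_acquisition()])
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix for this cell
#' @return invisibly, the sidecar path
#' @export
write_fret_acquisition <- function(sim, dir, prefix = "cell") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acq <- sim$acquisition
  panel <- sim$panel
  if (is.null(panel$shapes))
    stop("panel has no shape definitions; only shape-based panels can be ",
         "serialized")
  for (ch in channel_files)
    tiff::writeTIFF(quantize16(acq[[ch]]),
                    file.path(dir, paste0(prefix, "_", ch, ".tif")),
                    bits.per.sample = 16L)
  extra <- list(size = dim(acq$donor_pre),
                min_dist_um = panel$min_dist_um)
  if (!is.null(sim$ground_truth))
    extra$ground_truth <- unclass(sim$ground_truth)
  sidecar <- file.path(dir, paste0(prefix, "_rois.json"))
  write_roi_json(panel$shapes, acq$pixel_size_um, sidecar, extra = extra)
  invisible(sidecar)
}

#' @rdname fret_io
#' @return `read_fret_acquisition`: list with `acquisition`, `panel`, and
#'   `ground_truth` (NULL when absent from the sidecar)
#' @export
read_fret_acquisition <- function(dir, prefix = "cell") {
  sidecar <- file.path(dir, paste0(prefix, "_rois.json"))
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  imgs <- lapply(channel_files, function(ch) {
    f <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    round(tiff::readTIFF(f) * 65535)
  })
  names(imgs) <- channel_files
  acq <- fret_acquisition(imgs$donor_pre, imgs$donor_post,
                          imgs$acceptor_pre, imgs$acceptor_post,
                          meta$pixel_size_um)
  shapes <- lapply(meta$rois, shape_from_json)
  nr <- nrow(imgs$donor_pre); nc <- ncol(imgs$donor_pre)
  roi_names <- setdiff(names(shapes), c("bleach", "unbleached", "nucleus"))
  panel <- roi_panel(
    bleach_region = rasterize_shape(shapes$bleach, nr, nc),
    measurement_rois = lapply(shapes[roi_names], rasterize_shape,
                              nrow = nr, ncol = nc),
    unbleached_roi = rasterize_shape(shapes$unbleached, nr, nc),
    pixel_size_um = meta$pixel_size_um,
    min_dist_um = if (is.null(meta$min_dist_um)) 3 else meta$min_dist_um,
    shapes = shapes)
  gt <- if (!is.null(meta$ground_truth))
    do.call(ground_truth, meta$ground_truth) else NULL
  list(acquisition = acq, panel = panel, ground_truth = gt)
}

#' Write and load multi-cell datasets with a manifest
#'
#' `write_fret_dataset()` writes every cell of a dataset (TIFFs plus
#' sidecars) and a `manifest.csv` with columns `cell_id`, `condition`,
#' `prefix`. `load_fret_dataset()` reads a manifest back into the list
#' form [run_fret_pipeline()] consumes.
#'
#' @param cells dataset list (see [simulate_fret_experiment()])
#' @param dir dataset directory
#' @return the manifest path / the dataset list
#' @export
write_fret_dataset <- function(cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cells, function(cell) {
    write_fret_acquisition(cell, dir, prefix = cell$cell_id)
    data.frame(cell_id = cell$cell_id, condition = cell$condition,
               prefix = cell$cell_id, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_fret_dataset
#' @param manifest path to a manifest CSV
#' @export
load_fret_dataset <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(k) {
    cell <- read_fret_acquisition(dir, tab$prefix[k])
    cell$cell_id <- tab$cell_id[k]
    cell$condition <- tab$condition[k]
    cell
  })
}
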