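#' Shape and mask primitives
#'
#' Regions of interest are described as simple shapes (circles and
#' axis-aligned rectangles) and rasterized to logical pixel masks with the
#' center-in convention: a pixel belongs to a shape when its center does.
#' Pixel centers sit at integer coordinates `(x = column, y = row)`,
#' 1-based; serialized ROI coordinates are 0-based (see [write_roi_json()]).
#'
#' @param x,y center coordinates in pixel units
#' @param r radius in pixel units
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_circle <- function(x, y, r) {
  stopifnot(r > 0)
  structure(list(type = "circle", x = x, y = y, r = r), class = "fretab_shape")
}

#' @rdname shapes
#' @param xmin,xmax,ymin,ymax rectangle bounds in pixel units (inclusive of
#'   pixel centers falling inside)
#' @export
shape_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmin <= xmax, ymin <= ymax)
  structure(list(type = "rect", xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax), class = "fretab_shape")
}

#' Rasterize a shape to a logical mask
#'
#' @param shape a [shape_circle()] or [shape_rect()]
#' @param nrow,ncol mask dimensions in pixels
#' @return logical matrix, TRUE where the pixel center lies inside the shape
#' @export
rasterize_shape <- function(shape, nrow, ncol) {
  stopifnot(inherits(shape, "fretab_shape"))
  cx <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
  cy <- matrix(rep(seq_len(nrow), times = ncol), nrow, ncol)
  if (shape$type == "circle") {
    (cx - shape$x)^2 + (cy - shape$y)^2 <= shape$r^2
  } else {
    cx >= shape$xmin & cx <= shape$xmax & cy >= shape$ymin & cy <= shape$ymax
  }
}

#' Minimum edge-to-edge distance between two masks
#'
#' Distance between the closest pixel centers of two masks, in micrometers.
#' Used to enforce the rule that the unbleached reference region lies at
#' least 3 um away from the bleached region.
#'
#' @param mask_a,mask_b logical matrices of identical shape
#' @param pixel_size_um physical pixel size in micrometers
#' @return distance in um (Inf if either mask is empty)
#' @export
mask_distance_um <- function(mask_a, mask_b, pixel_size_um) {
  stopifnot(identical(dim(mask_a), dim(mask_b)), pixel_size_um > 0)
  ia <- which(mask_a, arr.ind = TRUE)
  ib <- which(mask_b, arr.ind = TRUE)
  if (nrow(ia) == 0L || nrow(ib) == 0L) return(Inf)
  dr <- outer(ia[, 1L], ib[, 1L], "-")
  dc <- outer(ia[, 2L], ib[, 2L], "-")
  sqrt(min(dr * dr + dc * dc)) * pixel_size_um
}

mask_subset <- function(inner, outer_mask) all(outer_mask[inner])
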