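#' Pearson co-localization coefficient over a mask
#'
#' The sample Pearson correlation of paired pixel intensities of two
#' channels under a mask (typically the whole nucleus), with no
#' thresholding — the plain coefficient a co-localization plugin reports
#' for an unthresholded region.
#'
#' @param channel_a,channel_b numeric matrices of identical shape
#' @param mask logical matrix selecting the pixels to correlate; `NULL`
#'   uses all pixels
#' @return Pearson R in `[-1, 1]`
#' @export
pearson_coefficient <- function(channel_a, channel_b, mask = NULL) {
  if (!identical(dim(channel_a), dim(channel_b)))
    stop("channel dimensions differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  if (!identical(dim(mask), dim(channel_a)))
    stop("mask dimensions differ from channels")
  if (!any(mask)) stop("mask is empty")
  a <- channel_a[mask]; b <- channel_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a channel under the mask")
  stats::cor(a, b)
}

bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  # pixel centers at integer (col = x, row = y); clamp to the center grid
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0, x0)];     i01 <- image[cbind(y0, x0 + 1L)]
  i10 <- image[cbind(y0 + 1L, x0)]; i11 <- image[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Intensity profile along a polyline
#'
#' Samples one or more channels by bilinear interpolation at a fixed step
#' along an ordered polyline, as an intensity line plot over a region of
#' interest. Distances are reported in pixels and micrometers.
#'
#' @param channels a single matrix or a named list of matrices
#' @param path numeric matrix with columns `x`, `y`: polyline vertices in
#'   pixel coordinates (pixel centers at integers, 1-based)
#' @param step sampling step along the path, pixels
#' @param pixel_size_um pixel size for the micrometer distance axis
#' @return data frame: `distance_px`, `distance_um`, one column per channel
#' @export
intensity_profile <- function(channels, path, step = 1,
                              pixel_size_um = 1) {
  if (is.matrix(channels)) channels <- list(intensity = channels)
  stopifnot(length(channels) >= 1L, step > 0)
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 2L)
    stop("path needs at least two (x, y) vertices")
  nr <- nrow(channels[[1L]]); nc <- ncol(channels[[1L]])
  if (any(path[, 1L] < 1 | path[, 1L] > nc |
          path[, 2L] < 1 | path[, 2L] > nr))
    stop("path vertex outside image bounds")
  seg_len <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  d <- seq(0, total, by = step)
  if (d[length(d)] < total) d <- c(d, total)
  seg_idx <- pmin(findInterval(d, cum, rightmost.closed = TRUE),
                  length(seg_len))
  t <- ifelse(seg_len[seg_idx] > 0,
              (d - cum[seg_idx]) / seg_len[seg_idx], 0)
  xs <- path[seg_idx, 1L] + t * diff(path[, 1L])[seg_idx]
  ys <- path[seg_idx, 2L] + t * diff(path[, 2L])[seg_idx]
  out <- data.frame(distance_px = d, distance_um = d * pixel_size_um)
  for (nm in names(channels))
    out[[nm]] <- bilinear_sample(channels[[nm]], xs, ys)
  out
}
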