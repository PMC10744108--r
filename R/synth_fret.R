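#' Ground truth for a synthetic acquisition
#'
#' The photophysical parameters a simulated cell is generated from. The
#' simulator models donor de-quenching only: inside the bleached region the
#' expected counts obey
#' \deqn{D_{pre} = D_0 (1 - E),\quad D_{post} = D_0 (1 - E (1 - B)),\quad
#'       A_{post} = A_{pre} (1 - B)}
#' so the apparent efficiency recovered by the acceptor-photobleaching
#' estimator \eqn{(D_{post}-D_{pre})/D_{post}} equals
#' \eqn{E B / (1 - E (1 - B))}, collapsing to \eqn{E} at complete bleach.
#'
#' @param E_true FRET efficiency in `[0, 1)`
#' @param B_true acceptor bleach fraction in `[0, 1]`
#' @param D0 mean donor photon count per pixel before quenching (> 0)
#' @param A0 mean acceptor photon count per pixel (> 0)
#' @param background constant background counts (>= 0)
#' @param read_noise_sd Gaussian read noise standard deviation, counts (>= 0)
#' @param seed integer seed for this acquisition's noise streams
#' @return an object of class `ground_truth`
#' @export
ground_truth <- function(E_true, B_true = 0.9, D0 = 1000, A0 = 1000,
                         background = 20, read_noise_sd = 3, seed = 1L) {
  if (!is.numeric(E_true) || E_true < 0 || E_true >= 1)
    stop("E_true must lie in [0, 1)")
  if (B_true < 0 || B_true > 1) stop("B_true must lie in [0, 1]")
  if (D0 <= 0 || A0 <= 0) stop("D0 and A0 must be positive")
  if (background < 0 || read_noise_sd < 0)
    stop("background and read_noise_sd must be nonnegative")
  structure(list(E_true = E_true, B_true = B_true, D0 = D0, A0 = A0,
                 background = background, read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Scene layout for a synthetic acquisition
#'
#' Geometry of one simulated nucleus: image size, pixel size, a circular
#' nucleus, a circular bleached region inside it, up to six circular
#' measurement ROIs inside the bleached region (placed on a hexagon plus
#' center), and a circular unbleached reference ROI at least `min_dist_um`
#' from the bleached region edge-to-edge.
#'
#' @param size image side length, pixels (square images)
#' @param pixel_size_um pixel size, micrometers
#' @param nucleus,bleach,unbleached circles ([shape_circle()])
#' @param n_rois number of measurement ROIs (1..6)
#' @param roi_radius measurement ROI radius, pixels
#' @param roi_ring radius of the hexagon the ROIs sit on, pixels
#' @param min_dist_um minimum unbleached-to-bleach distance, um
#' @return an object of class `scene_layout`
#' @export
scene_layout <- function(size = 128L, pixel_size_um = 0.1,
                         nucleus = shape_circle(64, 64, 52),
                         bleach = shape_circle(44, 64, 14),
                         unbleached = shape_circle(100, 64, 8),
                         n_rois = 6L, roi_radius = 3, roi_ring = 8,
                         min_dist_um = 3) {
  stopifnot(size >= 16L, pixel_size_um > 0, n_rois >= 1L, n_rois <= 6L,
            roi_radius > 0, roi_ring + roi_radius < bleach$r)
  layout <- structure(list(size = as.integer(size),
                           pixel_size_um = pixel_size_um,
                           nucleus = nucleus, bleach = bleach,
                           unbleached = unbleached,
                           n_rois = as.integer(n_rois),
                           roi_radius = roi_radius, roi_ring = roi_ring,
                           min_dist_um = min_dist_um),
                      class = "scene_layout")
  # building the panel validates containment and the distance constraint
  invisible(layout_panel(layout))
  layout
}

roi_shapes <- function(layout) {
  ang <- seq(0, by = pi / 3, length.out = 6L)
  xs <- layout$bleach$x + layout$roi_ring * cos(ang)
  ys <- layout$bleach$y + layout$roi_ring * sin(ang)
  shapes <- lapply(seq_len(layout$n_rois), function(k)
    shape_circle(xs[k], ys[k], layout$roi_radius))
  names(shapes) <- paste0("roi", seq_len(layout$n_rois))
  shapes
}

#' Build the ROI panel described by a scene layout
#'
#' @param layout a [scene_layout()]
#' @return a [roi_panel()]
#' @export
layout_panel <- function(layout) {
  n <- layout$size
  bleach_mask <- rasterize_shape(layout$bleach, n, n)
  nucleus_mask <- rasterize_shape(layout$nucleus, n, n)
  if (!mask_subset(bleach_mask, nucleus_mask))
    stop("bleached region must lie inside the nucleus")
  shapes <- roi_shapes(layout)
  rois <- lapply(shapes, rasterize_shape, nrow = n, ncol = n)
  unbleached_mask <- rasterize_shape(layout$unbleached, n, n)
  if (!mask_subset(unbleached_mask, nucleus_mask))
    stop("unbleached ROI must lie inside the nucleus")
  roi_panel(bleach_mask, rois, unbleached_mask,
            pixel_size_um = layout$pixel_size_um,
            min_dist_um = layout$min_dist_um,
            shapes = c(list(bleach = layout$bleach,
                            unbleached = layout$unbleached,
                            nucleus = layout$nucleus),
                       shapes))
}

# deterministic sub-stream seed per channel, kept inside 32-bit range
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

noisy_channel <- function(expected, gt, sub) {
  set.seed(substream_seed(gt$seed, sub))
  n <- length(expected)
  img <- stats::rpois(n, lambda = expected) +
    stats::rnorm(n, mean = 0, sd = gt$read_noise_sd) + gt$background
  matrix(pmax(img, 0), nrow = nrow(expected))
}

#' Simulate one acceptor-photobleaching acquisition
#'
#' Generates the four channel images of one cell under the donor
#' de-quenching model (see [ground_truth()]). Outside the bleached region
#' pre and post expectations are identical; sensitized emission and
#' acceptor cross-excitation are not modeled, matching the assumptions of
#' the donor-based estimator. Noise is Poisson shot noise on the expected
#' counts, additive Gaussian read noise, and a constant background.
#' Identical `(gt, layout)` pairs (including `gt$seed`) give bit-identical
#' images; per-channel noise comes from deterministic sub-streams of the
#' single top-level seed. The caller's RNG state is left untouched.
#'
#' @param gt a [ground_truth()]
#' @param layout a [scene_layout()]
#' @param noise simulate shot/read noise and background? With
#'   `noise = FALSE` the images are the exact noiseless expectations plus
#'   background.
#' @return list with elements `acquisition` ([fret_acquisition()]),
#'   `panel` ([roi_panel()]) and `ground_truth`
#' @export
simulate_fret_acquisition <- function(gt, layout = scene_layout(),
                                      noise = TRUE) {
  stopifnot(inherits(gt, "ground_truth"), inherits(layout, "scene_layout"))
  panel <- layout_panel(layout)
  n <- layout$size
  nucleus <- rasterize_shape(layout$nucleus, n, n)
  bleach <- panel$bleach_region

  E <- gt$E_true; B <- gt$B_true
  d_pre <- matrix(0, n, n); d_pre[nucleus] <- gt$D0 * (1 - E)
  d_post <- d_pre
  d_post[bleach] <- gt$D0 * (1 - E * (1 - B))
  a_pre <- matrix(0, n, n); a_pre[nucleus] <- gt$A0
  a_post <- a_pre
  a_post[bleach] <- gt$A0 * (1 - B)

  if (noise) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    d_pre <- noisy_channel(d_pre, gt, 1L)
    d_post <- noisy_channel(d_post, gt, 2L)
    a_pre <- noisy_channel(a_pre, gt, 3L)
    a_post <- noisy_channel(a_post, gt, 4L)
  } else {
    d_pre <- d_pre + gt$background; d_post <- d_post + gt$background
    a_pre <- a_pre + gt$background; a_post <- a_post + gt$background
  }

  list(acquisition = fret_acquisition(d_pre, d_post, a_pre, a_post,
                                      layout$pixel_size_um),
       panel = panel, ground_truth = gt)
}

#' Simulate a multi-condition acceptor-photobleaching experiment
#'
#' Generates `n_cells` acquisitions per condition from per-condition true
#' efficiencies, emulating the experimental designs of the interaction
#' study: binary FRET pairs against controls, third-partner competition,
#' and pathogenic-variant comparisons (see [fret_scenario()] for presets).
#'
#' @param conditions named numeric vector of true FRET efficiencies, one
#'   per condition label
#' @param n_cells cells per condition
#' @param layout a [scene_layout()]
#' @param seed top-level seed; every cell derives its own sub-seed
#' @param noise passed to [simulate_fret_acquisition()]
#' @param ... further arguments to [ground_truth()] (photon budget, noise
#'   levels, `B_true`)
#' @return list of cells, each a list with `cell_id`, `condition`,
#'   `acquisition`, `panel`, `ground_truth`
#' @export
simulate_fret_experiment <- function(conditions, n_cells = 3L,
                                     layout = scene_layout(), seed = 1L,
                                     noise = TRUE, ...) {
  stopifnot(is.numeric(conditions), !is.null(names(conditions)))
  cells <- list()
  k <- 0L
  for (cond in names(conditions)) {
    for (i in seq_len(n_cells)) {
      k <- k + 1L
      gt <- ground_truth(E_true = conditions[[cond]],
                         seed = substream_seed(seed, k), ...)
      sim <- simulate_fret_acquisition(gt, layout, noise = noise)
      cells[[k]] <- list(cell_id = sprintf("%s_cell%02d", cond, i),
                         condition = cond,
                         acquisition = sim$acquisition,
                         panel = sim$panel,
                         ground_truth = gt)
    }
  }
  cells
}

#' Scenario presets for synthetic experiments
#'
#' Named presets mirroring the study designs:
#' \describe{
#'   \item{binary}{one interacting FRET pair, the tandem positive control,
#'     and a non-interacting negative control.}
#'   \item{competition}{an interacting pair with and without a competing
#'     third partner generated at a 16\% relative reduction of the true
#'     efficiency, plus the positive control.}
#'   \item{variant}{wildtype pair versus two pathogenic variants with
#'     reduced efficiency, plus the positive control.}
#' }
#' The tandem-control efficiency defaults to 0.30.
#'
#' @param name preset name
#' @param E_pair true efficiency of the interacting pair
#' @param E_control true efficiency of the tandem positive control
#' @return named numeric vector of condition efficiencies suitable for
#'   [simulate_fret_experiment()]; the positive-control label is stored in
#'   attribute `control`
#' @export
fret_scenario <- function(name = c("binary", "competition", "variant"),
                          E_pair = 0.25, E_control = 0.30) {
  name <- match.arg(name)
  ctrl <- c(positive_control = E_control)
  out <- switch(name,
    binary = c(pair = E_pair, negative_control = 0, ctrl),
    competition = c(pair = E_pair, pair_with_competitor = E_pair * 0.84,
                    ctrl),
    variant = c(wildtype = E_pair, variant_1 = E_pair * 0.6,
                variant_2 = E_pair * 0.4, ctrl))
  attr(out, "control") <- "positive_control"
  out
}
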