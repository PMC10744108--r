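#' Simulate a two-channel co-localization image pair
#'
#' Inside the nucleus mask, pixel intensities of the two channels are drawn
#' from a bivariate Gaussian with the requested correlation and mapped to
#' positive intensities by a fixed affine transform; the sample Pearson
#' correlation over the mask therefore converges to `rho_target` as the
#' pixel count grows. Pixels outside the nucleus are zero. The default is
#' exact (no photon noise): adding shot noise would attenuate the realized
#' correlation below the target, which is not what a fixture with known
#' ground truth should do.
#'
#' @param rho_target target Pearson correlation, in `[-1, 1]`
#' @param layout a [scene_layout()]; only the nucleus and pixel grid are used
#' @param seed integer seed
#' @param mean_intensity,sd_intensity affine mapping of the unit-variance
#'   Gaussian field to counts
#' @return list with matrices `channel_a`, `channel_b`, the logical
#'   `nucleus` mask, `pixel_size_um`, and `rho_target`
#' @export
simulate_coloc_pair <- function(rho_target, layout = scene_layout(),
                                seed = 1L, mean_intensity = 1000,
                                sd_intensity = 200) {
  if (!is.numeric(rho_target) || length(rho_target) != 1L ||
      abs(rho_target) > 1)
    stop("rho_target must be a single correlation in [-1, 1]")
  n <- layout$size
  nucleus <- rasterize_shape(layout$nucleus, n, n)
  npx <- sum(nucleus)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(substream_seed(seed, 5L))
  z1 <- stats::rnorm(npx)
  z2 <- stats::rnorm(npx)
  zb <- rho_target * z1 + sqrt(1 - rho_target^2) * z2
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  a[nucleus] <- mean_intensity + sd_intensity * z1
  b[nucleus] <- mean_intensity + sd_intensity * zb
  list(channel_a = a, channel_b = b, nucleus = nucleus,
       pixel_size_um = layout$pixel_size_um, rho_target = rho_target)
}
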