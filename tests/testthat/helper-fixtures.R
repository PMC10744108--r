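# Fixture builders: tiny PDB files, PAE JSON files in both standard
# dialects, and hand-built acquisitions with exactly known ROI means.

write_toy_pdb <- function(file, atoms) {
  # atoms: data.frame(name, resid, chain, resno, x, y, z, b, elem)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, paste0(" ", a$name), a$resid, a$chain, a$resno,
            a$x, a$y, a$z, 1.00, a$b, a$elem)
  }, "")
  writeLines(c(lines, "END"), file)
  file
}

write_pae_json_nested <- function(file, mat) {
  obj <- list(list(predicted_aligned_error = mat,
                   max_predicted_aligned_error = max(mat)))
  jsonlite::write_json(obj, file, digits = NA)
  file
}

write_pae_json_flat <- function(file, mat) {
  L <- nrow(mat)
  idx <- expand.grid(r2 = seq_len(L), r1 = seq_len(L))  # row-major pairs
  obj <- list(list(residue1 = idx$r1, residue2 = idx$r2,
                   distance = mat[cbind(idx$r1, idx$r2)],
                   max_predicted_aligned_error = max(mat)))
  jsonlite::write_json(obj, file, digits = NA)
  file
}

# acquisition whose six 2x2 measurement ROIs have exactly the requested
# donor efficiencies, with acceptor bleach efficiency `bleach_pct` and an
# unbleached reference with efficiency `unbleached_eff`
handmade_acquisition <- function(roi_effs, bleach_pct = 80,
                                 unbleached_eff = 0.02) {
  n <- 40L
  d_post <- matrix(100, n, n)
  d_pre <- matrix(100, n, n)
  a_pre <- matrix(100, n, n)
  a_post <- matrix(100 * (1 - bleach_pct / 100), n, n)
  bleach <- fretab::shape_rect(2, 25, 2, 25)
  rois <- list()
  for (k in seq_along(roi_effs)) {
    x0 <- 3 + 4 * (k - 1)
    sh <- fretab::shape_rect(x0, x0 + 1, 5, 6)
    rois[[paste0("roi", k)]] <- sh
    m <- fretab::rasterize_shape(sh, n, n)
    d_pre[m] <- 100 * (1 - roi_effs[k])
  }
  unb_shape <- fretab::shape_rect(30, 36, 5, 12)
  unb <- fretab::rasterize_shape(unb_shape, n, n)
  d_pre[unb] <- 100 * (1 - unbleached_eff)
  a_post[unb] <- 100
  acq <- fretab::fret_acquisition(d_pre, d_post, a_pre, a_post,
                                  pixel_size_um = 1)
  panel <- fretab::roi_panel(
    bleach_region = fretab::rasterize_shape(bleach, n, n),
    measurement_rois = lapply(rois, fretab::rasterize_shape,
                              nrow = n, ncol = n),
    unbleached_roi = unb,
    pixel_size_um = 1)
  list(acquisition = acq, panel = panel)
}

# random acquisition + panel pair for oracle-agreement checks; bleach
# efficiencies of the ROIs straddle the 60% threshold
random_panel_case <- function() {
  n <- 40L
  bleach <- fretab::rasterize_shape(fretab::shape_rect(5, 25, 5, 25), n, n)
  k <- sample(1:6, 1L)
  rois <- lapply(seq_len(k), function(i) {
    x0 <- sample(5:23, 1L); y0 <- sample(5:23, 1L)
    fretab::rasterize_shape(fretab::shape_rect(x0, min(x0 + 2, 25),
                                               y0, min(y0 + 2, 25)), n, n)
  })
  names(rois) <- paste0("roi", seq_len(k))
  unb <- fretab::rasterize_shape(fretab::shape_rect(30, 36, 5, 12), n, n)
  a_pre <- matrix(runif(n * n, 0.5, 2), n, n)
  # per-pixel residual acceptor fraction 0.2..0.6 -> ROI bleach 40..80%
  a_post <- a_pre * matrix(runif(n * n, 0.2, 0.6), n, n)
  acq <- fretab::fret_acquisition(matrix(runif(n * n, 0.5, 2), n, n),
                                  matrix(runif(n * n, 0.5, 2), n, n),
                                  a_pre, a_post, pixel_size_um = 1)
  panel <- fretab::roi_panel(bleach, rois, unb, pixel_size_um = 1)
  list(acquisition = acq, panel = panel)
}
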