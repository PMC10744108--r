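test_that("roi_mean averages exactly the pixels under the mask", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] in row/col terms
  expect_equal(roi_mean(img, matrix(TRUE, 2, 2)), 2.5)
  expect_equal(roi_mean(matrix(7, 5, 5),
                        rasterize_shape(shape_circle(3, 3, 1.5), 5, 5)), 7)
  expect_error(roi_mean(img, matrix(FALSE, 2, 2)), "empty")
  expect_error(roi_mean(img, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("efficiency formulas follow the donor and acceptor definitions", {
  expect_equal(fret_efficiency(100, 100), 0)
  expect_equal(fret_efficiency(80, 100), 0.2)
  expect_equal(fret_efficiency(110, 100), -0.1)  # retained, not clamped
  expect_error(fret_efficiency(80, 0), "positive")

  expect_equal(bleach_efficiency(100, 0), 100)
  expect_equal(bleach_efficiency(100, 30), 70)
  expect_equal(bleach_efficiency(100, 50), 50)
  expect_error(bleach_efficiency(0, 10), "positive")
})

test_that("QC keeps strictly-above-threshold ROIs only", {
  m <- data.frame(roi_id = c("a", "b", "c", "d"),
                  bleach_eff = c(70, 65, 60, 50))
  kept <- qc_filter(m)
  expect_identical(kept$roi_id, c("a", "b"))  # exactly 60 is excluded
  expect_identical(nrow(qc_filter(m[0, , drop = FALSE])), 0L)
})

test_that("cell efficiency is the QC mean minus the unbleached reference", {
  hm <- handmade_acquisition(c(0.2, 0.22, 0.18, 0.20, 0.21, 0.19),
                             bleach_pct = 80, unbleached_eff = 0.02)
  res <- cell_efficiency(hm$acquisition, hm$panel)
  expect_equal(res$corrected_eff, 0.18, tolerance = 1e-12)
  expect_identical(res$n_rois_used, 6L)
  expect_true(res$reportable)

  # a single passing ROI is still reportable
  hm1 <- handmade_acquisition(0.3, bleach_pct = 80, unbleached_eff = 0)
  res1 <- cell_efficiency(hm1$acquisition, hm1$panel)
  expect_equal(res1$corrected_eff, 0.3, tolerance = 1e-12)
  expect_identical(res1$n_rois_used, 1L)

  # all ROIs failing QC flags the cell unreportable, never drops it
  hm0 <- handmade_acquisition(c(0.2, 0.25), bleach_pct = 50)
  res0 <- cell_efficiency(hm0$acquisition, hm0$panel)
  expect_false(res0$reportable)
  expect_identical(res0$n_rois_used, 0L)
  expect_true(is.na(res0$corrected_eff))
})

test_that("normalization divides by the positive-control mean", {
  tab <- data.frame(cell_id = c("c1", "c2", "s1"),
                    condition = c("ctrl", "ctrl", "sample"),
                    corrected_eff = c(0.2, 0.3, 0.1),
                    reportable = TRUE)
  out <- normalize_condition(tab, "ctrl")
  expect_equal(out$normalized_eff[3], 0.4)   # 0.1 / 0.25
  expect_equal(attr(out, "control_mean"), 0.25)

  tab2 <- data.frame(condition = "s", corrected_eff = 0.2,
                     reportable = TRUE)
  expect_error(normalize_condition(tab2, "ctrl"), "absent")
  tab3 <- data.frame(condition = c("ctrl", "s"),
                     corrected_eff = c(-0.1, 0.2), reportable = TRUE)
  expect_error(normalize_condition(tab3, "ctrl"), "positive")
})

test_that("QC and aggregation agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:60) {
    case <- random_panel_case()
    got <- cell_efficiency(case$acquisition, case$panel)
    want <- oracle_cell_eff(case$acquisition, case$panel)
    expect_identical(got$reportable, want$reportable)
    expect_identical(got$n_rois_used, want$n)
    if (want$reportable)
      expect_equal(got$corrected_eff, want$corrected, tolerance = 1e-12)
  }
})

test_that("noiseless two-condition pipeline normalizes to 1 and 0", {
  dataset <- simulate_fret_experiment(
    c(pair = 0.25, negative = 0), n_cells = 2L, seed = 3, noise = FALSE,
    B_true = 1, background = 0, read_noise_sd = 0)
  out <- run_fret_pipeline(dataset, control_label = "pair",
                           comparisons = NULL)
  means <- tapply(out$cells$normalized_eff, out$cells$condition, mean)
  expect_equal(unname(means["pair"]), 1, tolerance = 1e-9)
  expect_equal(unname(means["negative"]), 0, tolerance = 1e-9)
})

test_that("failed cells become flagged rows and the batch continues", {
  dataset <- simulate_fret_experiment(c(a = 0.2, b = 0.1), n_cells = 2L,
                                      seed = 5)
  # sabotage one cell with a zero-valued post-bleach donor channel
  bad <- dataset[[1L]]
  bad$acquisition$donor_post[] <- 0
  dataset[[1L]] <- bad
  out <- run_fret_pipeline(dataset, comparisons = NULL)
  expect_identical(nrow(out$cells), 4L)
  expect_false(out$cells$reportable[1L])
  expect_true(all(out$cells$reportable[-1L]))
})

test_that("negative-control datasets center on zero efficiency", {
  est <- vapply(1:10, function(s) {
    sim <- simulate_fret_acquisition(ground_truth(0, seed = s))
    cell_efficiency(sim$acquisition, sim$panel)$corrected_eff
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 2 * se + 1e-4)
})
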