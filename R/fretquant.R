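#' Mean intensity under an ROI mask
#'
#' @param image numeric matrix
#' @param roi_mask logical matrix of the same shape
#' @return arithmetic mean of the pixel values under the mask
#' @export
roi_mean <- function(image, roi_mask) {
  if (!identical(dim(image), dim(roi_mask)))
    stop("image and ROI mask dimensions differ")
  if (!any(roi_mask)) stop("ROI mask is empty")
  mean(image[roi_mask])
}

#' FRET efficiency from donor de-quenching
#'
#' The acceptor-photobleaching estimator: the fractional donor intensity
#' increase after acceptor bleaching,
#' \deqn{E = (D_{post} - D_{pre}) / D_{post}.}
#' Negative values (donor loss) are returned as-is, never clamped: the
#' later subtraction of an unbleached reference region can legitimately
#' yield negative corrected efficiencies.
#'
#' @param D_pre,D_post mean donor intensities before/after bleaching
#' @return dimensionless efficiency
#' @export
fret_efficiency <- function(D_pre, D_post) {
  if (any(D_post <= 0)) stop("D_post must be positive")
  (D_post - D_pre) / D_post
}

#' Acceptor bleach efficiency in percent
#'
#' \deqn{B = (1 - A_{post} / A_{pre}) \times 100,} i.e. 100 at complete
#' bleach. Used for quality control: only ROIs bleached above a threshold
#' carry a meaningful de-quenching signal.
#'
#' @param A_pre,A_post mean acceptor intensities before/after bleaching
#' @return percent bleached
#' @export
bleach_efficiency <- function(A_pre, A_post) {
  if (any(A_pre <= 0)) stop("A_pre must be positive")
  (1 - A_post / A_pre) * 100
}

#' Quality-control filter on ROI measurements
#'
#' Retains exactly the measurements whose bleach efficiency is strictly
#' greater than the threshold (default 60 percent).
#'
#' @param measurements data frame with a `bleach_eff` column (as produced
#'   by [measure_rois()])
#' @param threshold_percent QC threshold, percent
#' @return the retained rows
#' @export
qc_filter <- function(measurements, threshold_percent = 60) {
  stopifnot(is.data.frame(measurements))
  measurements[measurements$bleach_eff > threshold_percent, , drop = FALSE]
}

#' Per-ROI measurements of one acquisition
#'
#' Computes mean channel intensities, FRET efficiency, bleach efficiency
#' and the QC flag for every measurement ROI of a panel.
#'
#' @param acquisition a [fret_acquisition()]
#' @param panel a [roi_panel()]
#' @param qc_threshold bleach-efficiency QC threshold, percent
#' @return data frame with one row per measurement ROI: `roi_id`, `D_pre`,
#'   `D_post`, `A_pre`, `A_post`, `fret_eff`, `bleach_eff`, `qc_pass`
#' @export
measure_rois <- function(acquisition, panel, qc_threshold = 60) {
  stopifnot(inherits(acquisition, "fret_acquisition"),
            inherits(panel, "roi_panel"))
  rows <- lapply(names(panel$measurement_rois), function(id) {
    m <- panel$measurement_rois[[id]]
    dpre <- roi_mean(acquisition$donor_pre, m)
    dpost <- roi_mean(acquisition$donor_post, m)
    apre <- roi_mean(acquisition$acceptor_pre, m)
    apost <- roi_mean(acquisition$acceptor_post, m)
    be <- bleach_efficiency(apre, apost)
    data.frame(roi_id = id, D_pre = dpre, D_post = dpost,
               A_pre = apre, A_post = apost,
               fret_eff = fret_efficiency(dpre, dpost),
               bleach_eff = be, qc_pass = be > qc_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Corrected FRET efficiency of one cell
#'
#' The mean efficiency of the QC-passing measurement ROIs minus the
#' efficiency of the unbleached reference ROI (computed with the identical
#' estimator). Cells with no QC-passing ROI are flagged unreportable, not
#' dropped silently.
#'
#' @param acquisition a [fret_acquisition()]
#' @param panel a [roi_panel()]
#' @param cell_id identifier recorded in the result
#' @param condition condition label recorded in the result
#' @param qc_threshold bleach-efficiency QC threshold, percent
#' @return one-row data frame: `cell_id`, `condition`, `corrected_eff`,
#'   `unbleached_eff`, `n_rois_used`, `reportable`
#' @export
cell_efficiency <- function(acquisition, panel, cell_id = "cell",
                            condition = NA_character_, qc_threshold = 60) {
  meas <- measure_rois(acquisition, panel, qc_threshold)
  kept <- qc_filter(meas, qc_threshold)
  unb <- fret_efficiency(roi_mean(acquisition$donor_pre, panel$unbleached_roi),
                         roi_mean(acquisition$donor_post, panel$unbleached_roi))
  if (nrow(kept) == 0L) {
    return(data.frame(cell_id = cell_id, condition = condition,
                      corrected_eff = NA_real_, unbleached_eff = unb,
                      n_rois_used = 0L, reportable = FALSE,
                      stringsAsFactors = FALSE))
  }
  data.frame(cell_id = cell_id, condition = condition,
             corrected_eff = mean(kept$fret_eff) - unb,
             unbleached_eff = unb, n_rois_used = nrow(kept),
             reportable = TRUE, stringsAsFactors = FALSE)
}

#' Normalize a condition table by a positive-control condition
#'
#' Adds `normalized_eff = corrected_eff / mean(corrected_eff of control)`,
#' the normalization to the tandem donor-acceptor positive control.
#'
#' @param table data frame of cell results (rows from [cell_efficiency()])
#' @param control_label condition label of the positive control
#' @return `table` with a `normalized_eff` column and attribute
#'   `control_mean`
#' @export
normalize_condition <- function(table, control_label) {
  stopifnot(is.data.frame(table))
  ctrl <- table$corrected_eff[table$condition == control_label &
                                table$reportable]
  if (length(ctrl) == 0L)
    stop("control condition '", control_label, "' absent or unreportable")
  cm <- mean(ctrl)
  if (cm <= 0) stop("control condition mean efficiency must be positive")
  table$normalized_eff <- table$corrected_eff / cm
  attr(table, "control_mean") <- cm
  table
}

#' Run the full quantification over a multi-cell dataset
#'
#' Quantifies every cell, assembles the per-cell condition table,
#' optionally normalizes by the positive control, summarizes each
#' condition, and compares conditions with the configured nonparametric
#' test. Per-cell failures become flagged unreportable rows; the batch
#' never aborts.
#'
#' @param dataset list of cells as produced by
#'   [simulate_fret_experiment()]: each element has `cell_id`,
#'   `condition`, `acquisition`, `panel`
#' @param control_label positive-control condition for normalization, or
#'   `NULL` to skip normalization
#' @param qc_threshold bleach-efficiency QC threshold, percent
#' @param test `"signed-rank"` or `"rank-sum"`, passed to
#'   [compare_conditions()]
#' @param comparisons either `"all-vs-first"` (every condition against the
#'   first non-control condition) or a list of `c(a, b)` label pairs;
#'   `NULL` for no testing
#' @return list with `cells` (per-cell table), `summary` (per-condition
#'   boxplot statistics), and `stats` (pairwise test results)
#' @export
run_fret_pipeline <- function(dataset, control_label = NULL,
                              qc_threshold = 60, test = "signed-rank",
                              comparisons = "all-vs-first") {
  stopifnot(length(dataset) >= 1L)
  rows <- lapply(dataset, function(cell) {
    res <- try(cell_efficiency(cell$acquisition, cell$panel,
                               cell_id = cell$cell_id,
                               condition = cell$condition,
                               qc_threshold = qc_threshold), silent = TRUE)
    if (inherits(res, "try-error")) {
      data.frame(cell_id = cell$cell_id, condition = cell$condition,
                 corrected_eff = NA_real_, unbleached_eff = NA_real_,
                 n_rois_used = 0L, reportable = FALSE,
                 stringsAsFactors = FALSE)
    } else res
  })
  cells <- do.call(rbind, rows)
  if (!is.null(control_label))
    cells <- normalize_condition(cells, control_label)

  value_col <- if (!is.null(control_label)) "normalized_eff" else
    "corrected_eff"
  conds <- unique(cells$condition)
  summaries <- lapply(conds, function(cc) {
    v <- cells[[value_col]][cells$condition == cc & cells$reportable]
    if (length(v) == 0L) return(NULL)
    s <- boxplot_summary(v)
    data.frame(condition = cc, n = length(v), mean = mean(v),
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n_outliers = length(s$outliers), stringsAsFactors = FALSE)
  })
  summary_tab <- do.call(rbind, summaries)

  stats_tab <- NULL
  if (!is.null(comparisons)) {
    pairs <- if (identical(comparisons, "all-vs-first")) {
      base_cond <- setdiff(conds, control_label)[1L]
      others <- setdiff(conds, c(base_cond))
      lapply(others, function(o) c(base_cond, o))
    } else comparisons
    stats_rows <- lapply(pairs, function(p) {
      xa <- cells[[value_col]][cells$condition == p[1L] & cells$reportable]
      xb <- cells[[value_col]][cells$condition == p[2L] & cells$reportable]
      if (length(xa) == 0L || length(xb) == 0L) return(NULL)
      compare_conditions(xa, xb, labels = p, test = test)
    })
    stats_tab <- do.call(rbind, stats_rows)
  }

  list(cells = cells, summary = summary_tab, stats = stats_tab)
}
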