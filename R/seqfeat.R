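#' Consensus calling of intrinsically disordered regions
#'
#' A residue is flagged disordered when its disorder score is strictly
#' above 0.5 or its predicted-structure confidence (pLDDT) is strictly
#' below 50; residues exactly at 0.5 / 50 are not flagged. Maximal runs of
#' flagged residues of at least `min_len` residues are returned as
#' segments. Either track may be absent, in which case the rule degrades
#' to the present track.
#'
#' @param disorder per-residue disorder scores in `[0, 1]`, or `NULL`
#' @param plddt per-residue confidence in `[0, 100]`, or `NULL`
#' @param min_len minimal segment length, residues; short flag runs are
#'   treated as noise and suppressed
#' @param disorder_threshold,plddt_threshold the two decision boundaries
#' @return data frame of segments: `start`, `end` (1-based inclusive),
#'   `length`, `mean_disorder`, `mean_plddt`
#' @export
call_idrs <- function(disorder = NULL, plddt = NULL, min_len = 5L,
                      disorder_threshold = 0.5, plddt_threshold = 50) {
  if (is.null(disorder) && is.null(plddt))
    stop("at least one of disorder and plddt is required")
  if (!is.null(disorder) && !is.null(plddt) &&
      length(disorder) != length(plddt))
    stop("disorder and plddt tracks differ in length")
  if (!is.null(disorder) && any(disorder < 0 | disorder > 1))
    stop("disorder scores must lie in [0, 1]")
  if (!is.null(plddt) && any(plddt < 0 | plddt > 100))
    stop("pLDDT values must lie in [0, 100]")
  L <- length(if (is.null(disorder)) plddt else disorder)
  flag <- rep(FALSE, L)
  if (!is.null(disorder)) flag <- flag | (disorder > disorder_threshold)
  if (!is.null(plddt)) flag <- flag | (plddt < plddt_threshold)
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  seg <- data.frame(start = starts[keep], end = ends[keep])
  seg$length <- seg$end - seg$start + 1L
  seg$mean_disorder <- vapply(seq_len(nrow(seg)), function(k) {
    if (is.null(disorder)) NA_real_ else
      mean(disorder[seg$start[k]:seg$end[k]])
  }, numeric(1))
  seg$mean_plddt <- vapply(seq_len(nrow(seg)), function(k) {
    if (is.null(plddt)) NA_real_ else mean(plddt[seg$start[k]:seg$end[k]])
  }, numeric(1))
  seg
}

aa_classes <- list(hydrophobic = strsplit("AVLIMFWYC", "")[[1L]],
                   positive = c("K", "R", "H"),
                   negative = c("D", "E"),
                   polar = c("S", "T", "N", "Q"),
                   special = c("G", "P"))

aa_class_of <- local({
  map <- character(0)
  for (cl in names(aa_classes)) map[aa_classes[[cl]]] <- cl
  map
})

#' Per-column conservation profile of a multiple sequence alignment
#'
#' Columns where the reference sequence has a gap are dropped, so profile
#' coordinates equal reference residue numbers (regions absent from the
#' reference are excluded from the analysis). The default score of a
#' column is the fraction of its non-gap residues falling in the column's
#' majority physicochemical class (hydrophobic AVLIMFWYC, positive KRH,
#' negative DE, polar STNQ, special GP); `method = "identity"` scores the
#' fraction of the single most frequent residue instead.
#'
#' @param msa named character vector of aligned sequences (equal lengths,
#'   gap `-`), or a `Biostrings::AAStringSet` / `AAMultipleAlignment`
#' @param reference_id name of the reference sequence
#' @param threshold columns with `score >= threshold` are flagged conserved
#' @param method `"class"` (majority physicochemical class) or
#'   `"identity"`
#' @return data frame: `position` (reference residue number),
#'   `reference_aa`, `score`, `gap_fraction`, `conserved`
#' @export
conservation_profile <- function(msa, reference_id, threshold = 0.8,
                                 method = c("class", "identity")) {
  method <- match.arg(method)
  seqs <- msa_to_character(msa)
  if (length(seqs) == 0L) stop("empty alignment")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  if (!reference_id %in% names(seqs))
    stop("reference sequence '", reference_id, "' not in alignment")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  ref <- mat[reference_id, ]
  keep <- ref != "-"
  mat <- mat[, keep, drop = FALSE]
  ref <- ref[keep]
  nseq <- nrow(mat)
  score <- numeric(ncol(mat)); gapf <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gaps <- col == "-"
    gapf[j] <- mean(gaps)
    res <- col[!gaps]
    if (length(res) == 0L) { score[j] <- 0; next }
    grp <- if (method == "class") {
      cl <- aa_class_of[res]
      cl[is.na(cl)] <- "other"
      cl
    } else res
    score[j] <- max(table(grp)) / length(res)
  }
  data.frame(position = seq_along(ref), reference_aa = ref,
             score = score, gap_fraction = gapf,
             conserved = score >= threshold, stringsAsFactors = FALSE)
}

msa_to_character <- function(msa) {
  if (is.character(msa)) return(msa)
  if (inherits(msa, "AAMultipleAlignment"))
    msa <- Biostrings::unmasked(msa)
  if (inherits(msa, "XStringSet")) {
    out <- as.character(msa)
    names(out) <- names(msa)
    return(out)
  }
  stop("unsupported MSA representation")
}

#' Read an aligned FASTA file
#'
#' @param file path to an aligned FASTA file
#' @return named character vector of aligned sequences
#' @export
read_msa <- function(file) {
  s <- Biostrings::readAAStringSet(file)
  out <- as.character(s)
  # keep only the identifier token of each FASTA header
  names(out) <- vapply(strsplit(names(s), "\\s+"), `[`, "", 1L)
  out
}

#' Das-Pappu diagram-of-states charge classification
#'
#' Computes the fractions of positively (K, R) and negatively (D, E)
#' charged residues (histidine is treated as neutral at physiological
#' pH), the fraction of charged residues FCR = f+ + f-, the net charge
#' per residue NCPR = f+ - f-, and the diagram-of-states region:
#' \describe{
#'   \item{R1}{f+ < 0.25 and f- < 0.25 — weak polyampholytes and
#'     polyelectrolytes (globules and tadpoles).}
#'   \item{R2}{f+ <= 0.35 and f- <= 0.35 otherwise — the boundary
#'     ("Janus") region; conformation is context dependent.}
#'   \item{R3}{f+ > 0.35 and f- > 0.35 — strong polyampholytes (coils,
#'     hairpins, chimeras).}
#'   \item{R4}{f- > 0.35, f+ <= 0.35 — negatively charged strong
#'     polyelectrolytes.}
#'   \item{R5}{f+ > 0.35, f- <= 0.35 — positively charged strong
#'     polyelectrolytes.}
#' }
#' The five regions tile the whole (f+, f-) simplex exclusively.
#'
#' @param sequence amino-acid string or character vector of residues
#' @param window optional `c(start, end)` restricting the analysis to a
#'   subsequence (1-based inclusive)
#' @param on_nonstandard `"skip"` drops non-standard letters from the
#'   denominator; `"error"` rejects them
#' @return list: `f_plus`, `f_minus`, `FCR`, `NCPR`, `region` (`"R1"` ..
#'   `"R5"`), `label` (human-readable class), `n` (residues scored)
#' @export
charge_classify <- function(sequence, window = NULL,
                            on_nonstandard = c("skip", "error")) {
  on_nonstandard <- match.arg(on_nonstandard)
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1L]] else
    sequence
  aa <- toupper(aa)
  if (!is.null(window)) {
    stopifnot(window[1L] >= 1L, window[2L] <= length(aa))
    aa <- aa[window[1L]:window[2L]]
  }
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  bad <- !(aa %in% standard)
  if (any(bad)) {
    if (on_nonstandard == "error")
      stop("non-standard residue letter(s): ",
           paste(unique(aa[bad]), collapse = ", "))
    aa <- aa[!bad]
  }
  n <- length(aa)
  if (n == 0L) stop("no standard residues to classify")
  f_plus <- mean(aa %in% c("K", "R"))
  f_minus <- mean(aa %in% c("D", "E"))
  region <- das_pappu_region(f_plus, f_minus)
  labels <- c(R1 = "weak polyampholyte/polyelectrolyte",
              R2 = "Janus (boundary) sequence",
              R3 = "strong polyampholyte",
              R4 = "negative polyelectrolyte",
              R5 = "positive polyelectrolyte")
  list(f_plus = f_plus, f_minus = f_minus, FCR = f_plus + f_minus,
       NCPR = f_plus - f_minus, region = region,
       label = unname(labels[region]), n = n)
}

#' @rdname charge_classify
#' @param f_plus,f_minus charged-residue fractions
#' @export
das_pappu_region <- function(f_plus, f_minus) {
  stopifnot(f_plus >= 0, f_minus >= 0, f_plus + f_minus <= 1 + 1e-12)
  if (f_plus < 0.25 && f_minus < 0.25) "R1"
  else if (f_plus <= 0.35 && f_minus <= 0.35) "R2"
  else if (f_plus > 0.35 && f_minus > 0.35) "R3"
  else if (f_minus > 0.35) "R4"
  else "R5"
}
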