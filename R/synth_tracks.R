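#' Simulate paired disorder and pLDDT tracks with known IDR segments
#'
#' Generates one disorder score (0..1) and one pLDDT value (0..100) per
#' residue such that every residue inside a declared segment satisfies the
#' disorder consensus rule (disorder strictly above 0.5 or pLDDT strictly
#' below 50) and every residue outside satisfies neither. Scores are drawn
#' uniformly well away from the decision boundaries so the ground-truth
#' segmentation is unambiguous.
#'
#' @param length sequence length (residues)
#' @param idr_segments two-column matrix or list of `c(start, end)` pairs,
#'   1-based inclusive, non-overlapping, within `[1, length]`
#' @param seed integer seed
#' @return list with numeric vectors `disorder` and `plddt` (length
#'   `length`) and the validated `segments` matrix
#' @export
simulate_tracks <- function(length, idr_segments = NULL, seed = 1L) {
  stopifnot(length >= 1L)
  seg <- normalize_segments(idr_segments, length)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(substream_seed(seed, 6L))
  inside <- rep(FALSE, length)
  if (nrow(seg) > 0L)
    for (k in seq_len(nrow(seg))) inside[seg[k, 1L]:seg[k, 2L]] <- TRUE
  disorder <- ifelse(inside, stats::runif(length, 0.60, 0.95),
                     stats::runif(length, 0.05, 0.40))
  plddt <- ifelse(inside, stats::runif(length, 20, 45),
                  stats::runif(length, 55, 95))
  list(disorder = disorder, plddt = plddt, segments = seg)
}

normalize_segments <- function(idr_segments, length) {
  if (is.null(idr_segments) || (is.list(idr_segments) &&
                                length(idr_segments) == 0L))
    return(matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("start", "end"))))
  seg <- if (is.matrix(idr_segments)) idr_segments else
    do.call(rbind, idr_segments)
  seg <- matrix(as.integer(seg), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (any(seg[, 1L] > seg[, 2L])) stop("segment start exceeds end")
  if (any(seg < 1L) || any(seg > length))
    stop("segments must lie within [1, length]")
  seg <- seg[order(seg[, 1L]), , drop = FALSE]
  if (nrow(seg) > 1L && any(seg[-1L, 1L] <= seg[-nrow(seg), 2L]))
    stop("segments must not overlap")
  seg
}

#' Simulate a block-structured PAE matrix for a two-chain complex
#'
#' Builds a square predicted-aligned-error matrix with low values inside
#' chains, a configurable inter-chain level, and an optional confident
#' interface block between two residue intervals — the pattern a confident
#' complex prediction shows in its PAE plot.
#'
#' @param chain_lengths named integer vector of chain lengths (>= 2 chains
#'   supported; names become chain ids)
#' @param intra mean PAE within a chain (Angstrom)
#' @param inter mean PAE between chains (Angstrom)
#' @param interface optional list with `a` and `b` ([residue_interval()])
#'   and `value`, setting both rectangular interface blocks to `value`
#' @param jitter half-width of uniform jitter added to every entry
#' @param seed integer seed
#' @return a [pae_matrix()]
#' @export
simulate_pae <- function(chain_lengths, intra = 4, inter = 25,
                         interface = NULL, jitter = 0, seed = 1L) {
  stopifnot(!is.null(names(chain_lengths)), all(chain_lengths >= 1))
  L <- sum(chain_lengths)
  ends <- cumsum(chain_lengths)
  starts <- ends - chain_lengths + 1L
  chains <- Map(function(s, e) c(s, e), starts, ends)
  names(chains) <- names(chain_lengths)
  m <- matrix(inter, L, L)
  for (k in seq_along(chains)) {
    idx <- chains[[k]][1L]:chains[[k]][2L]
    m[idx, idx] <- intra
  }
  if (!is.null(interface)) {
    ia <- interval_rows(interface$a, chains)
    ib <- interval_rows(interface$b, chains)
    m[ia, ib] <- interface$value
    m[ib, ia] <- interface$value
  }
  if (jitter > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(substream_seed(seed, 7L))
    m <- m + matrix(stats::runif(L * L, -jitter, jitter), L, L)
    m <- pmax(m, 0)
  }
  pae_matrix(m, chains)
}
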