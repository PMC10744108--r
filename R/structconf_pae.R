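#' Predicted-aligned-error matrix with chain ranges
#'
#' A square matrix of expected position errors (Angstrom, >= 0) for a
#' predicted structure, annotated with the 1-based inclusive residue
#' interval each chain occupies in matrix coordinates. Chain ranges must
#' partition `1..L`.
#'
#' @param matrix square numeric matrix of PAE values (Angstrom)
#' @param chains named list, chain id -> `c(start, end)` in matrix
#'   coordinates
#' @return an object of class `pae_matrix`
#' @export
pae_matrix <- function(matrix, chains) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("PAE matrix must be square")
  if (any(matrix < 0)) stop("PAE entries must be nonnegative")
  L <- nrow(matrix)
  if (is.null(names(chains)) || any(names(chains) == ""))
    stop("chains must be a named list")
  rng <- do.call(rbind, lapply(chains, function(x) as.integer(x[1:2])))
  rng <- rng[order(rng[, 1L]), , drop = FALSE]
  covered <- unname(unlist(Map(seq, rng[, 1L], rng[, 2L])))
  if (length(covered) != L || !all(sort(covered) == seq_len(L)))
    stop("chain ranges must partition 1..", L)
  structure(list(matrix = matrix, L = L, chains = chains),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, chains: %s\n", x$L, x$L,
              paste(sprintf("%s[%d-%d]", names(x$chains),
                            vapply(x$chains, `[`, 1L, i = 1L),
                            vapply(x$chains, `[`, 1L, i = 2L)),
                    collapse = ", ")))
  invisible(x)
}

#' Residue interval on a chain
#'
#' @param chain chain identifier
#' @param start,end 1-based inclusive residue positions within the chain
#' @return an object of class `residue_interval`
#' @export
residue_interval <- function(chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || start > end) stop("need 1 <= start <= end")
  structure(list(chain = chain, start = start, end = end),
            class = "residue_interval")
}

# matrix rows covered by a chain-local interval
interval_rows <- function(interval, chains) {
  stopifnot(inherits(interval, "residue_interval") ||
              (is.list(interval) && !is.null(interval$chain)))
  rng <- chains[[interval$chain]]
  if (is.null(rng)) stop("unknown chain '", interval$chain, "'")
  len <- rng[2L] - rng[1L] + 1L
  if (interval$end > len)
    stop(sprintf("interval %d-%d exceeds chain %s length %d",
                 interval$start, interval$end, interval$chain, len))
  (rng[1L] - 1L) + interval$start:interval$end
}

#' Read a predicted-aligned-error JSON file
#'
#' Accepts the two standard layouts: the nested-list dialect (a
#' `predicted_aligned_error` or `pae` field holding an L x L list of
#' lists, possibly wrapped in a one-element array) and the flat dialect
#' (`residue1`, `residue2`, `distance` parallel arrays). Chain ranges come
#' from the `chains` argument or from a companion model file.
#'
#' @param file path to the JSON file
#' @param chains named list chain id -> `c(start, end)`; or `NULL` with
#'   `model` given
#' @param model optional path to a PDB/mmCIF model whose chain lengths
#'   define the ranges
#' @return a [pae_matrix()]
#' @export
read_pae <- function(file, chains = NULL, model = NULL) {
  obj <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (is.data.frame(obj)) obj <- as.list(obj)
  # unwrap the one-element-array wrapper some pipelines emit
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L)
    obj <- obj[[1L]]
  m <- NULL
  for (key in c("predicted_aligned_error", "pae")) {
    if (!is.null(obj[[key]])) {
      v <- obj[[key]]
      if (is.list(v) && length(v) == 1L && is.matrix(v[[1L]])) v <- v[[1L]]
      if (is.list(v)) v <- do.call(rbind, v)
      m <- as.matrix(v)
      break
    }
  }
  if (is.null(m) && !is.null(obj$distance)) {
    r1 <- unlist(obj$residue1); r2 <- unlist(obj$residue2)
    d <- unlist(obj$distance)
    L <- max(r1, r2)
    if (length(d) != L * L)
      stop("flat PAE arrays do not fill a square matrix")
    m <- matrix(NA_real_, L, L)
    m[cbind(r1, r2)] <- d
  }
  if (is.null(m)) stop("no recognizable PAE payload in ", file)
  if (nrow(m) != ncol(m)) stop("PAE matrix is not square")
  if (anyNA(m)) stop("PAE matrix has missing entries")
  if (is.null(chains)) {
    if (is.null(model)) {
      chains <- list(A = c(1L, nrow(m)))
    } else {
      chains <- model_chain_ranges(model)
    }
  }
  pae_matrix(m, chains)
}

model_chain_ranges <- function(model) {
  trk <- plddt_track(model)
  lens <- table(factor(trk$chain, levels = unique(trk$chain)))
  ends <- cumsum(as.integer(lens))
  starts <- ends - as.integer(lens) + 1L
  out <- Map(function(s, e) c(s, e), starts, ends)
  names(out) <- names(lens)
  out
}

#' Mean PAE over an interface block
#'
#' The arithmetic mean of the rectangular PAE block with rows from
#' interval `a` and columns from interval `b` — the mean over the
#' corresponding area of the PAE plot. With `symmetric = TRUE` the mean is
#' taken over the entries of both rectangles (`a` rows x `b` columns and
#' `b` rows x `a` columns).
#'
#' @param pae a [pae_matrix()]
#' @param a,b [residue_interval()]s (chain-local coordinates)
#' @param symmetric average over both off-diagonal rectangles?
#' @return mean PAE in Angstrom
#' @export
pae_region_mean <- function(pae, a, b, symmetric = FALSE) {
  stopifnot(inherits(pae, "pae_matrix"))
  ra <- interval_rows(a, pae$chains)
  rb <- interval_rows(b, pae$chains)
  block <- pae$matrix[ra, rb, drop = FALSE]
  if (!symmetric) return(mean(block))
  block2 <- pae$matrix[rb, ra, drop = FALSE]
  mean(c(block, block2))
}
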