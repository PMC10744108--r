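#' Detect van der Waals contacts between atoms
#'
#' Two atoms are in contact when their van der Waals overlap
#' \eqn{r_i + r_j - d_{ij}} meets the cutoff (inclusive; the default
#' -0.4 Angstrom is the conventional "contact" criterion, a mild negative
#' overlap rather than a steric clash). Pairs within the same residue and
#' directly bonded pairs (non-hydrogen atoms closer than `bond_dist`) are
#' excluded. Candidate pairs are found with a cell-list spatial partition
#' whose cell edge equals the largest possible contact distance, so the
#' result is identical to exhaustive all-pairs search.
#'
#' @param atoms an [atom_set()]
#' @param overlap_cutoff contact threshold on the overlap, Angstrom
#'   (pairs with `overlap >= overlap_cutoff` are retained)
#' @param hbond_allowance subtracted from the overlap before comparison
#'   (0 for contact mode)
#' @param bond_dist non-hydrogen pairs closer than this are treated as
#'   covalently bonded and excluded, Angstrom
#' @return data frame of contacts: atom indices `i`, `j`, chain/residue/
#'   atom-name identifiers for both, `distance`, `overlap`, sorted by
#'   `(i, j)`
#' @export
find_contacts <- function(atoms, overlap_cutoff = -0.4,
                          hbond_allowance = 0, bond_dist = 1.9) {
  stopifnot(inherits(atoms, "atom_set"))
  at <- atoms$atoms
  n <- nrow(at)
  r <- unname(atoms$radii[at$elem])
  empty <- contact_frame(at, integer(0), integer(0), numeric(0), numeric(0))
  if (n < 2L) return(empty)
  # largest distance any pair could have and still be a contact
  dmax <- 2 * max(r) - overlap_cutoff + hbond_allowance + 1e-6
  cand <- cell_list_pairs(at$x, at$y, at$z, dmax)
  if (nrow(cand) == 0L) return(empty)
  i <- cand[, 1L]; j <- cand[, 2L]
  d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
              (at$z[i] - at$z[j])^2)
  overlap <- r[i] + r[j] - d - hbond_allowance
  keep <- overlap >= overlap_cutoff - 1e-9
  # same-residue and covalently bonded exclusions
  same_res <- at$chain[i] == at$chain[j] & at$resno[i] == at$resno[j]
  bonded <- d < bond_dist & at$elem[i] != "H" & at$elem[j] != "H"
  keep <- keep & !same_res & !bonded
  i <- i[keep]; j <- j[keep]
  ord <- order(i, j)
  contact_frame(at, i[ord], j[ord], d[keep][ord], overlap[keep][ord])
}

contact_frame <- function(at, i, j, d, overlap) {
  data.frame(i = i, j = j,
             chain_i = at$chain[i], resno_i = at$resno[i],
             name_i = at$name[i],
             chain_j = at$chain[j], resno_j = at$resno[j],
             name_j = at$name[j],
             distance = d, overlap = overlap, stringsAsFactors = FALSE)
}

# All index pairs (i < j) whose separation can be <= dmax, via a cubic
# cell list: atoms are binned into cells of edge dmax; only pairs within a
# cell or between lexicographically forward neighbor cells are candidates.
cell_list_pairs <- function(x, y, z, dmax) {
  ix <- floor(x / dmax); iy <- floor(y / dmax); iz <- floor(z / dmax)
  ix <- ix - min(ix); iy <- iy - min(iy); iz <- iz - min(iz)
  nx <- max(ix) + 1; ny <- max(iy) + 1; nz <- max(iz) + 1
  id <- ix + nx * (iy + ny * iz)
  cells <- split(seq_along(x), id)
  cid <- as.numeric(names(cells))
  cz <- cid %/% (nx * ny); rem <- cid %% (nx * ny)
  cy <- rem %/% nx; cx <- rem %% nx
  # within-cell pairs
  multi <- cells[lengths(cells) > 1L]
  out_i <- list(); out_j <- list(); k <- 0L
  for (a in multi) {
    prs <- utils::combn(a, 2L)
    k <- k + 1L; out_i[[k]] <- prs[1L, ]; out_j[[k]] <- prs[2L, ]
  }
  # forward neighbor offsets (13 of the 26 neighbors)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  fwd <- offs[offs[, 1L] > 0 |
                (offs[, 1L] == 0 & offs[, 2L] > 0) |
                (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0), ,
              drop = FALSE]
  for (m in seq_len(nrow(fwd))) {
    px <- cx + fwd[m, 1L]; py <- cy + fwd[m, 2L]; pz <- cz + fwd[m, 3L]
    ok <- px >= 0 & px < nx & py >= 0 & py < ny & pz >= 0 & pz < nz
    nid <- px + nx * (py + ny * pz)
    nb <- match(nid, cid)
    src <- which(ok & !is.na(nb))
    for (s in src) {
      a <- cells[[s]]; b <- cells[[nb[s]]]
      k <- k + 1L
      out_i[[k]] <- rep(a, each = length(b))
      out_j[[k]] <- rep(b, times = length(a))
    }
  }
  if (k == 0L) return(matrix(integer(0), 0L, 2L))
  i <- unlist(out_i); j <- unlist(out_j)
  cbind(pmin(i, j), pmax(i, j))
}

#' Interface residues implied by inter-chain contacts
#'
#' Restricts a contact table to contacts between two chains and reports,
#' per chain, the sorted unique contacting residues and the minimal
#' covering interval — the residue stretches forming the binding site.
#'
#' @param contacts contact table from [find_contacts()]
#' @param chain_a,chain_b the two chain identifiers
#' @return list with one element per chain: `residues` (sorted unique) and
#'   `interval` (`c(start, end)` or `NULL` when no contacts)
#' @export
interface_residues <- function(contacts, chain_a, chain_b) {
  sel <- (contacts$chain_i == chain_a & contacts$chain_j == chain_b) |
    (contacts$chain_i == chain_b & contacts$chain_j == chain_a)
  cc <- contacts[sel, , drop = FALSE]
  res_for <- function(ch) {
    r <- sort(unique(c(cc$resno_i[cc$chain_i == ch],
                       cc$resno_j[cc$chain_j == ch])))
    list(residues = r,
         interval = if (length(r) > 0L) c(min(r), max(r)) else NULL)
  }
  out <- list(res_for(chain_a), res_for(chain_b))
  names(out) <- c(chain_a, chain_b)
  out
}
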