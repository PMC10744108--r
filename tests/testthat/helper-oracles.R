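# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive each quantity from first
# principles and stay free of the code paths they check.

# two-sided exact signed-rank p by explicit enumeration of all 2^n sign
# assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# exhaustive all-pairs contact detection over the full distance matrix
oracle_contacts <- function(atoms_df, radii, cutoff = -0.4,
                            bond_dist = 1.9) {
  d <- sqrt(outer(atoms_df$x, atoms_df$x, "-")^2 +
              outer(atoms_df$y, atoms_df$y, "-")^2 +
              outer(atoms_df$z, atoms_df$z, "-")^2)
  r <- unname(radii[atoms_df$elem])
  ov <- outer(r, r, "+") - d
  reskey <- paste(atoms_df$chain, atoms_df$resno)
  same <- outer(reskey, reskey, "==")
  nonH <- atoms_df$elem != "H"
  bonded <- d < bond_dist & outer(nonH, nonH, "&")
  keep <- ov >= cutoff - 1e-9 & !same & !bonded
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  data.frame(i = idx[, 1L], j = idx[, 2L],
             distance = d[idx], overlap = ov[idx])
}

# per-residue IDR rule followed by an explicit run scan
oracle_idrs <- function(disorder, plddt, min_len = 5L) {
  flag <- (disorder > 0.5) | (plddt < 50)
  segs <- NULL
  start <- NA_integer_
  for (i in seq_along(flag)) {
    if (flag[i] && is.na(start)) start <- i
    if ((!flag[i] || i == length(flag)) && !is.na(start)) {
      end <- if (flag[i]) i else i - 1L
      if (end - start + 1L >= min_len)
        segs <- rbind(segs, c(start, end))
      start <- NA_integer_
    }
  }
  if (is.null(segs)) matrix(integer(0), 0L, 2L) else segs
}

# independent re-derivation of per-cell corrected efficiency from masks
oracle_cell_eff <- function(acq, panel, threshold = 60) {
  effs <- c(); n_used <- 0L
  for (m in panel$measurement_rois) {
    apre <- sum(acq$acceptor_pre[m]) / sum(m)
    apost <- sum(acq$acceptor_post[m]) / sum(m)
    if ((1 - apost / apre) * 100 > threshold) {
      dpre <- sum(acq$donor_pre[m]) / sum(m)
      dpost <- sum(acq$donor_post[m]) / sum(m)
      effs <- c(effs, (dpost - dpre) / dpost)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) return(list(reportable = FALSE, n = 0L))
  u <- panel$unbleached_roi
  updre <- sum(acq$donor_pre[u]) / sum(u)
  updost <- sum(acq$donor_post[u]) / sum(u)
  list(reportable = TRUE, n = n_used,
       corrected = sum(effs) / n_used - (updost - updre) / updost)
}

# apparent efficiency the acceptor-photobleaching estimator should
# recover at partial bleach
apparent_eff <- function(E, B) E * B / (1 - E * (1 - B))

# diagram-of-states predicates, written out independently; exactly one
# must hold for any admissible (f+, f-)
oracle_das_pappu_flags <- function(fp, fm) {
  r1 <- fp < 0.25 && fm < 0.25
  r2 <- !r1 && fp <= 0.35 && fm <= 0.35
  r3 <- fp > 0.35 && fm > 0.35
  r4 <- fm > 0.35 && fp <= 0.35
  r5 <- fp > 0.35 && fm <= 0.35
  c(R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5)
}
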