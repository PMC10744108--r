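test_that("both PAE JSON dialects load to the identical matrix", {
  set.seed(1)
  m <- matrix(round(runif(16, 0, 30), 2), 4, 4)
  f1 <- write_pae_json_nested(tempfile(fileext = ".json"), m)
  f2 <- write_pae_json_flat(tempfile(fileext = ".json"), m)
  p1 <- read_pae(f1)
  p2 <- read_pae(f2)
  expect_equal(p1$matrix, p2$matrix, ignore_attr = TRUE)
  expect_equal(p1$matrix, m, ignore_attr = TRUE)

  # non-square payloads are rejected
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = matrix(1, 4, 5)), bad)
  expect_error(read_pae(bad), "square")
})

test_that("chain ranges must partition the matrix", {
  m <- matrix(1, 4, 4)
  expect_error(pae_matrix(m, list(A = c(1, 2))), "partition")
  expect_error(pae_matrix(m, list(A = c(1, 2), B = c(2, 4))), "partition")
  ok <- pae_matrix(m, list(A = c(1, 2), B = c(3, 4)))
  expect_s3_class(ok, "pae_matrix")
})

test_that("PAE region means reproduce hand-computed block means", {
  m <- matrix(0, 4, 4)
  m[1:2, 3:4] <- c(10, 8, 12, 10)   # block rows 1:2 x cols 3:4
  m[3:4, 1:2] <- 6
  m[1:2, 1:2] <- 2; m[3:4, 3:4] <- 3
  pae <- pae_matrix(m, list(A = c(1, 2), B = c(3, 4)))
  a <- residue_interval("A", 1, 2); b <- residue_interval("B", 1, 2)
  expect_equal(pae_region_mean(pae, a, b), 10)
  expect_equal(pae_region_mean(pae, a, b, symmetric = TRUE), 8)
  # constant matrix gives the constant for any block
  pc <- pae_matrix(matrix(7.5, 6, 6), list(A = c(1, 3), B = c(4, 6)))
  expect_equal(pae_region_mean(pc, residue_interval("A", 2, 3),
                               residue_interval("B", 1, 2)), 7.5)
  expect_error(pae_region_mean(pae, residue_interval("A", 1, 3), b),
               "exceeds")
})

test_that("PAE block means match brute force and nest under union", {
  set.seed(8)
  for (rep in 1:20) {
    L <- sample(6:20, 1)
    m <- matrix(runif(L * L, 0, 30), L, L)
    split_at <- sample(2:(L - 2), 1)
    pae <- pae_matrix(m, list(A = c(1, split_at),
                              B = c(split_at + 1, L)))
    a <- sort(sample(seq_len(split_at), 2))
    lb <- L - split_at
    b <- sort(sample(seq_len(lb), 2))
    got <- pae_region_mean(pae, residue_interval("A", a[1], a[2]),
                           residue_interval("B", b[1], b[2]))
    want <- mean(m[a[1]:a[2], split_at + (b[1]:b[2])])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # full-matrix region equals the global mean
  m <- matrix(runif(64, 0, 30), 8, 8)
  pae <- pae_matrix(m, list(A = c(1, 8)))
  expect_equal(pae_region_mean(pae, residue_interval("A", 1, 8),
                               residue_interval("A", 1, 8)), mean(m))
  # the union mean lies between the two block means (weighted average)
  a1 <- mean(m[1:3, 1:8]); a2 <- mean(m[4:8, 1:8])
  u <- pae_region_mean(pae, residue_interval("A", 1, 8),
                       residue_interval("A", 1, 8))
  expect_gte(u, min(a1, a2)); expect_lte(u, max(a1, a2))
})

test_that("pLDDT extraction follows the CA-representative convention", {
  f <- tempfile(fileext = ".pdb")
  atoms <- data.frame(
    name = c("N", "CA", "CB", "CA", "P"),
    resid = c("ALA", "ALA", "ALA", "GLY", "LIG"),
    chain = c("A", "A", "A", "A", "B"),
    resno = c(1, 1, 1, 3, 1),
    x = c(0, 1, 2, 4, 9), y = 0, z = 0,
    b = c(80, 70, 60, 90, 55),
    elem = c("N", "C", "C", "C", "P"), stringsAsFactors = FALSE)
  write_toy_pdb(f, atoms)
  trk <- plddt_track(f)
  expect_equal(trk$plddt[trk$chain == "A" & trk$resno == 1], 70)  # CA not CB
  expect_equal(trk$plddt[trk$chain == "A" & trk$resno == 3], 90)
  expect_equal(trk$plddt[trk$chain == "B"], 55)  # first atom, no CA
  expect_equal(attr(trk, "gaps")$A, 2)           # missing residue 2

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(plddt_track(empty))
})

test_that("contact detection applies the overlap criterion inclusively", {
  mk <- function(d) atom_set(data.frame(
    elem = c("C", "C"), x = c(0, d), y = 0, z = 0,
    chain = c("A", "B"), resno = c(1, 2)))
  expect_identical(nrow(find_contacts(mk(10))), 0L)
  hit <- find_contacts(mk(3.0))
  expect_equal(hit$overlap, 0.4)
  expect_equal(hit$distance, 3.0)
  # boundary pair at overlap exactly -0.4 is retained
  edge <- find_contacts(mk(3.8))
  expect_identical(nrow(edge), 1L)
  expect_equal(edge$overlap, -0.4)
  expect_identical(nrow(find_contacts(mk(3.81))), 0L)
})

test_that("same-residue and bonded pairs are excluded", {
  same_res <- atom_set(data.frame(elem = c("C", "C"), x = c(0, 3),
                                  y = 0, z = 0, chain = "A", resno = 1))
  expect_identical(nrow(find_contacts(same_res)), 0L)
  bonded <- atom_set(data.frame(elem = c("C", "N"), x = c(0, 1.33),
                                y = 0, z = 0, chain = "A",
                                resno = c(1, 2)))
  expect_identical(nrow(find_contacts(bonded)), 0L)
  # hydrogens at bonding distance are not treated as covalent partners
  h <- atom_set(data.frame(elem = c("C", "H"), x = c(0, 1.5),
                           y = 0, z = 0, chain = c("A", "B"),
                           resno = c(1, 2)))
  expect_identical(nrow(find_contacts(h)), 1L)
})

test_that("unknown elements are rejected up front", {
  expect_error(atom_set(data.frame(elem = "Xx", x = 0, y = 0, z = 0,
                                   chain = "A", resno = 1)), "radius")
})

test_that("cell-list contact search equals the all-pairs oracle", {
  radii <- vdw_radii()
  set.seed(13)
  for (rep in 1:15) {
    n <- 120
    atoms_df <- data.frame(
      elem = sample(c("C", "N", "O", "S"), n, replace = TRUE),
      x = runif(n, 0, 18), y = runif(n, 0, 18), z = runif(n, 0, 18),
      chain = sample(c("A", "B"), n, replace = TRUE),
      resno = sample(1:40, n, replace = TRUE), stringsAsFactors = FALSE)
    got <- find_contacts(atom_set(atoms_df))
    want <- oracle_contacts(atoms_df, radii)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$overlap, want$overlap, tolerance = 1e-12)
  }
})

test_that("interface residues cover exactly the inter-chain contacts", {
  contacts <- data.frame(
    chain_i = c("A", "A", "A", "A"), resno_i = c(140, 141, 165, 7),
    chain_j = c("B", "B", "B", "A"), resno_j = c(301, 310, 301, 8))
  out <- interface_residues(contacts, "A", "B")
  expect_identical(out$A$residues, c(140, 141, 165))
  expect_identical(out$A$interval, c(140, 165))
  expect_identical(out$B$residues, c(301, 310))
  # intra-chain contact (7-8 within A) contributed nothing
  none <- interface_residues(contacts[4, , drop = FALSE], "A", "B")
  expect_identical(none$A$residues, numeric(0))
  expect_null(none$A$interval)
})
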