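test_that("IDR consensus flags by strict thresholds and min length", {
  expect_equal(call_idrs(rep(0.9, 10), rep(40, 10))$start, 1)
  expect_equal(call_idrs(rep(0.9, 10), rep(40, 10))$end, 10)

  # residues exactly at 0.5 / 50 are never flagged
  seg <- call_idrs(rep(0.5, 20), rep(50, 20), min_len = 1)
  expect_identical(nrow(seg), 0L)

  # exact segment recovery
  disorder <- rep(0.2, 50); disorder[c(10:20, 35:40)] <- 0.8
  plddt <- rep(80, 50)
  seg2 <- call_idrs(disorder, plddt)
  expect_equal(seg2$start, c(10, 35))
  expect_equal(seg2$end, c(20, 40))

  # runs shorter than min_len are suppressed
  d3 <- rep(0.2, 30); d3[5:7] <- 0.9
  expect_identical(nrow(call_idrs(d3, rep(80, 30), min_len = 5)), 0L)
  expect_identical(nrow(call_idrs(d3, rep(80, 30), min_len = 3)), 1L)

  # either track alone drives the degraded rule
  expect_equal(call_idrs(disorder = rep(0.9, 6))$end, 6)
  expect_equal(call_idrs(plddt = rep(30, 6))$end, 6)
  expect_error(call_idrs(rep(0.2, 5), rep(80, 6)), "length")
})

test_that("IDR segmentation equals the brute-force rule on random tracks", {
  set.seed(21)
  for (rep in 1:50) {
    L <- sample(20:120, 1)
    disorder <- runif(L)
    plddt <- runif(L, 0, 100)
    got <- call_idrs(disorder, plddt)
    want <- oracle_idrs(disorder, plddt)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
    }
  }
})

test_that("conservation profile scores majority physicochemical class", {
  msa <- c(human = "LKD-A", mouse = "LKDEA", frog = "LDDEA",
           fish = "LDS-A")
  prof <- conservation_profile(msa, "human")
  # column 4 (reference gap) dropped: positions follow the reference
  expect_identical(nrow(prof), 4L)
  expect_identical(prof$reference_aa, c("L", "K", "D", "A"))
  expect_equal(prof$score[1], 1)          # all hydrophobic L
  expect_equal(prof$score[2], 0.5)        # 2 positive K vs 2 negative D
  expect_equal(prof$score[3], 0.75)       # D, D, D vs one polar S
  expect_equal(prof$gap_fraction, rep(0, 4))
})

test_that("mixed-class columns score the majority fraction", {
  rows <- c(rep("K", 5), rep("D", 5))
  msa <- setNames(rows, paste0("s", 1:10))
  msa <- c(ref = "K", msa)
  prof <- conservation_profile(msa, "ref")
  expect_equal(prof$score, 6 / 11)  # 6 K+ref positive of 11 non-gap
})

test_that("conservation is row-order invariant and reference-anchored", {
  msa <- c(ref = "AK-LM", s1 = "GKQLM", s2 = "AKELV", s3 = "A-ELM")
  p1 <- conservation_profile(msa, "ref")
  p2 <- conservation_profile(msa[c(3, 1, 4, 2)], "ref")
  expect_equal(p1, p2)
  # adding a duplicate reference row never decreases any column score
  p3 <- conservation_profile(c(msa, ref2 = unname(msa["ref"])), "ref")
  expect_true(all(p3$score >= p1$score - 1e-12))
  expect_error(conservation_profile(msa, "missing"), "reference")
  expect_error(conservation_profile(character(0), "ref"), "empty")
})

test_that("identity scoring and thresholds are available", {
  msa <- c(ref = "AA", s1 = "AV", s2 = "AV", s3 = "AV")
  cls <- conservation_profile(msa, "ref", method = "class")
  ident <- conservation_profile(msa, "ref", method = "identity")
  expect_equal(cls$score[2], 1)      # A and V share the hydrophobic class
  expect_equal(ident$score[2], 0.75) # but only 3/4 are the same residue
  expect_identical(conservation_profile(msa, "ref",
                                        threshold = 0.8)$conserved,
                   c(TRUE, TRUE))
  expect_identical(ident$conserved, c(TRUE, FALSE))
})

test_that("aligned FASTA round-trips through read_msa", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">human some description", "LKD-A", ">mouse", "LKDEA"), f)
  msa <- read_msa(f)
  expect_identical(names(msa), c("human", "mouse"))
  expect_identical(unname(msa[1]), "LKD-A")
})

test_that("charge classification reproduces the diagram-of-states calls", {
  pg <- charge_classify(strrep("G", 20))
  expect_equal(pg$FCR, 0); expect_equal(pg$NCPR, 0)
  expect_identical(pg$region, "R1")

  janus <- charge_classify(paste0(strrep("K", 6), "D", strrep("G", 13)))
  expect_equal(janus$f_plus, 0.3)
  expect_equal(janus$f_minus, 0.05)
  expect_equal(janus$FCR, 0.35)
  expect_equal(janus$NCPR, 0.25)
  expect_identical(janus$region, "R2")
  expect_match(janus$label, "Janus")

  pe <- charge_classify(strrep("E", 20))
  expect_identical(pe$region, "R4")
  expect_identical(charge_classify(strrep("K", 20))$region, "R5")
  expect_identical(charge_classify(strrep("KD", 10))$region, "R3")

  # histidine counts as neutral
  expect_equal(charge_classify(strrep("H", 10))$FCR, 0)
})

test_that("windows and non-standard residues are handled explicitly", {
  s <- paste0(strrep("G", 10), strrep("K", 10))
  expect_equal(charge_classify(s, window = c(11, 20))$f_plus, 1)
  expect_error(charge_classify("KXDE", on_nonstandard = "error"), "X")
  skip_version <- charge_classify("KXDE", on_nonstandard = "skip")
  expect_equal(skip_version$n, 3)
  expect_equal(skip_version$f_minus, 2 / 3)
})

test_that("regions tile the charge simplex exclusively", {
  for (fp in seq(0, 1, by = 0.05)) {
    for (fm in seq(0, 1 - fp, by = 0.05)) {
      flags <- oracle_das_pappu_flags(fp, fm)
      expect_identical(sum(flags), 1L)
      expect_identical(das_pappu_region(fp, fm), names(which(flags)))
    }
  }
})
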