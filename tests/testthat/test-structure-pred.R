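test_that("Chou-Fasman assigns canonical formers and breakers", {
  # Val: strongest strand former; strand beats helix on summed propensity
  expect_equal(predict_secondary_structure(strrep("V", 10))$frac_E, 1)
  # Pro/Gly: breakers for both states
  expect_equal(predict_secondary_structure("PPPPGGGGPPPP")$frac_E, 0)
  expect_equal(predict_secondary_structure("PPPPGGGGPPPP")$frac_C, 1)
  # Glu: strong helix former, strand breaker
  ss <- predict_secondary_structure(strrep("E", 12))
  expect_equal(ss$frac_H, 1)
  expect_equal(ss$frac_E, 0)
})

test_that("secondary-structure fractions always partition the sequence", {
  set.seed(3)
  for (i in 1:25) {
    s <- random_seq(sample(1:300, 1))
    ss <- predict_secondary_structure(s)
    expect_equal(ss$frac_H + ss$frac_E + ss$frac_C, 1, tolerance = 1e-9)
    expect_length(ss$states, nchar(s))
    # deterministic
    expect_identical(ss, predict_secondary_structure(s))
  }
  short <- predict_secondary_structure("MKVGL")
  expect_true(short$too_short)
  expect_equal(short$frac_C, 1)
})

test_that("signal-peptide rules reproduce the worked example", {
  s <- paste0("MKKLLLLLLLLAHAAEF", strrep("DGEKS", 6))
  sp <- detect_signal_peptide(s)
  expect_true(sp$present)
  expect_equal(sp$cleavage_after, 14L)
  expect_equal(unname(sp$h_region), c(4L, 12L))

  # no hydrophobic stretch at all
  expect_false(detect_signal_peptide(strrep("EDG", 20))$present)

  # too-short sequences are never called
  sp <- detect_signal_peptide("MKKLLLLLLLLAHAA")
  expect_false(sp$present)
  expect_true(sp$too_short)
})

test_that("signal detection ignores everything after residue 45", {
  set.seed(5)
  for (i in 1:10) {
    head45 <- paste0("MKR", random_seq(42))
    a <- paste0(head45, random_seq(100))
    b <- paste0(head45, strrep("W", 80))
    expect_identical(detect_signal_peptide(a), detect_signal_peptide(b))
  }
})

test_that("planted porin signals are recovered at the planted site", {
  for (s in c(1, 2, 3, 10, 77)) {
    p <- make_porin(s)
    sp <- detect_signal_peptide(p$sequence)
    expect_true(sp$present)
    expect_lte(abs(sp$cleavage_after - p$truth$cleavage_after), 2L)
  }
})

test_that("globularity separates ordered from disorder-biased sequences", {
  # disorder-promoting repeat climbs: never globular
  expect_false(assess_globularity(strrep("ESPG", 25))$globular)

  # hydrophobic-core composition, 30% I/L/V/F spread along the chain: every
  # 15-residue window then carries >= 4 core residues (sum ~ -1.4) against a
  # mildly positive remainder, so the smoothed sum is downhill throughout
  ilvf <- rep(c("I", "L", "V", "F"), length.out = 30)
  rest <- rep(c("A", "G", "S", "T", "K", "E", "D", "N", "Q", "Y"),
              length.out = 70)
  pos <- round(seq(1, 100, length.out = 30))
  s <- character(100)
  s[pos] <- ilvf
  s[setdiff(1:100, pos)] <- rest
  g <- assess_globularity(paste(s, collapse = ""))
  expect_true(g$globular)
  expect_equal(g$coverage, 1)

  # randomly shuffled draws of the same composition hover near the
  # detection margin: a clear majority, but not all, are called globular
  set.seed(9)
  hits <- 0L
  for (i in 1:20) {
    core <- c(sample(c("I", "L", "V", "F"), 30, replace = TRUE),
              sample(setdiff(AA_ALPHABET, c("I", "L", "V", "F")), 70,
                     replace = TRUE))
    hits <- hits + assess_globularity(paste(sample(core), collapse = ""))$globular
  }
  expect_gte(hits, 12L)
  # too short to host a domain of the minimum length
  expect_false(assess_globularity(random_seq(20), min_len = 40)$globular)
  g <- assess_globularity("", min_len = 40)
  expect_false(g$globular)
  expect_equal(g$coverage, 0)
})

test_that("globularity domains are disjoint and coverage is consistent", {
  set.seed(21)
  for (i in 1:10) {
    s <- make_decoy(i, "globular")$sequence
    g <- assess_globularity(s)
    if (nrow(g$domains) > 1) {
      expect_true(all(diff(as.vector(t(g$domains))) > 0))
    }
    if (nrow(g$domains)) {
      expect_true(all(g$domains[, "end"] - g$domains[, "start"] + 1 >= 40))
    }
    expect_equal(g$coverage,
                 sum(g$domains[, "end"] - g$domains[, "start"] + 1) /
                   nchar(s))
  }
})

test_that("concatenating two globular sequences stays near-globular", {
  # coverage of the concatenation may lose at most roughly one smoothing
  # window plus one minimum-length run at the junction
  for (s in c(2, 4, 6)) {
    a <- make_decoy(s, "globular")$sequence
    b <- make_decoy(s + 50, "globular")$sequence
    ga <- assess_globularity(a)
    gb <- assess_globularity(b)
    gab <- assess_globularity(paste0(a, b))
    slack <- (15 + 40) / (nchar(a) + nchar(b))
    expect_gte(gab$coverage, min(ga$coverage, gb$coverage) - slack)
  }
})

test_that("synthetic beta-rich porins are strand- rather than helix-rich", {
  for (s in 1:5) {
    ss <- predict_secondary_structure(make_porin(s)$sequence)
    expect_gt(ss$frac_E, ss$frac_H)
  }
})
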