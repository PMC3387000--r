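test_that("global alignment matches published BLOSUM62 diagonal sums", {
  r <- global_align("MKV", "MKV")
  expect_equal(r$score, 14)  # 5 + 5 + 4
  expect_equal(r$identity, 1)
  expect_error(global_align("A", ""), "non-empty")
})

test_that("gapped strings reconstruct the inputs and scores are symmetric", {
  set.seed(19)
  for (i in 1:15) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    r <- global_align(a, b)
    expect_equal(nchar(r$aligned_a), nchar(r$aligned_b))
    expect_equal(gsub("-", "", r$aligned_a), a)
    expect_equal(gsub("-", "", r$aligned_b), b)
    expect_equal(r$score, global_align(b, a)$score)
    expect_gte(r$identity, 0)
    expect_lte(r$identity, 1)
  }
})

test_that("alignment equals the exhaustive-enumeration oracle on tiny pairs", {
  alpha <- c("A", "R", "N", "D")
  # exhaustive over all pairs of length <= 2, sampled pairs up to length 6
  seqs <- c(alpha, apply(expand.grid(alpha, alpha), 1, paste, collapse = ""))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(global_align(a, b)$score, bf_align_score(a, b),
                   info = paste(a, b))
    }
  }
  set.seed(23)
  for (i in 1:40) {
    a <- random_seq(sample(3:6, 1), alphabet = alpha)
    b <- random_seq(sample(3:6, 1), alphabet = alpha)
    expect_equal(global_align(a, b)$score, bf_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("family clustering is single-linkage and order-independent", {
  recs <- c(a = "MKVLLDEGKTTTWNP", b = "MKVLLDEGKTTTWNP", c = "WWPPHHRRCCYYGG")
  fam <- cluster_families(recs, 0.5)
  expect_equal(unname(fam[c("a", "b")]), c("a", "a"))
  expect_false(fam[["c"]] == "a")

  # order independence
  fam2 <- cluster_families(recs[c(3, 1, 2)], 0.5)
  expect_equal(fam2[names(fam)], fam)

  # transitive chain a~b, b~c links all three even if a!~c directly:
  # single linkage only needs one linking path
  set.seed(31)
  s <- strrep("MKVLYDEGHTRWNPQA", 3)
  half1 <- paste0(substr(s, 1, 24), random_seq(24))
  half2 <- paste0(random_seq(24), substr(s, 25, 48))
  fam <- cluster_families(c(x = s, y = half1, z = half2),
                          identity_threshold = 0.4)
  expect_length(unique(fam), 1L)

  # unrelated random sequences split apart
  set.seed(37)
  fam <- cluster_families(c(p = random_seq(80), q = random_seq(80)),
                          identity_threshold = 0.30)
  expect_length(unique(fam), 2L)
})

test_that("syntenic blocks are found in order, with analogs flagged", {
  gt <- data.frame(
    genome_id = "g1",
    locus_tag = paste0("g1_", 0:5),
    ordinal = 0:5,
    strand = "+",
    family = c("x", "secG", "tyrS", "ompA", "ompB", "y"),
    stringsAsFactors = FALSE
  )
  b <- find_syntenic_blocks(gt)
  expect_length(b, 1L)
  expect_true(is.na(b[[1]]$analog_slot))
  expect_equal(b[[1]]$loci$family, c("secG", "tyrS", "ompA", "ompB"))
  expect_true(b[[1]]$same_strand)

  # analog: the porin slot holds a gene from no pattern family
  gt$family <- c("x", "secG", "tyrS", "ompA", "", "y")
  b <- find_syntenic_blocks(gt)
  expect_length(b, 1L)
  expect_equal(b[[1]]$analog_slot, "g1_4")

  # scattered families: no block
  gt$family <- c("secG", "x", "tyrS", "ompA", "x", "ompB")
  expect_length(find_syntenic_blocks(gt), 0L)

  expect_error(find_syntenic_blocks(gt, pattern = c("secG", "")), "family")
  expect_error(find_syntenic_blocks(gt, pattern = c("secG", "secG")),
               "distinct")
})

test_that("block finding is invariant to genome reversal with strand flip", {
  gm <- make_genome_map(seed = 5)
  fwd <- find_syntenic_blocks(gm$genes)
  expect_length(fwd, 1L)

  rev_genes <- gm$genes
  rev_genes$ordinal <- max(rev_genes$ordinal) - rev_genes$ordinal
  rev_genes$strand <- ifelse(rev_genes$strand == "+", "-", "+")
  bwd <- find_syntenic_blocks(rev_genes)
  expect_length(bwd, 1L)
  expect_equal(bwd[[1]]$orientation, "reverse")
  expect_setequal(bwd[[1]]$loci$locus_tag, fwd[[1]]$loci$locus_tag)

  # renaming the genome changes nothing but the label
  renamed <- gm$genes
  renamed$genome_id <- "other_name"
  b <- find_syntenic_blocks(renamed)
  expect_length(b, 1L)
  expect_equal(b[[1]]$loci$family, fwd[[1]]$loci$family)
})

test_that("analog verdicts require the anchoring signature plus 3 criteria", {
  refs <- test_references()
  gm <- make_genome_map(seed = 7, with_analog = TRUE)
  blocks <- find_syntenic_blocks(gm$genes)
  expect_length(blocks, 1L)
  expect_false(is.na(blocks[[1]]$analog_slot))

  sc <- screen_proteome(gm$proteins, refs)
  fa <- flag_analogs(blocks, sc)
  expect_equal(nrow(fa), 1L)
  expect_equal(fa$verdict, "putative analog porin")

  # an analog slot failing the C-terminus rule is unresolved
  sc2 <- sc
  sc2$cterm_ok[sc2$id == blocks[[1]]$analog_slot] <- FALSE
  expect_equal(flag_analogs(blocks, sc2)$verdict, "unresolved")

  # missing screening result is an error
  sc3 <- sc[sc$id != blocks[[1]]$analog_slot, ]
  expect_error(flag_analogs(blocks, sc3), "no screening result")

  # no analog slots -> empty result
  gm0 <- make_genome_map(seed = 7, with_analog = FALSE)
  b0 <- find_syntenic_blocks(gm0$genes)
  expect_equal(nrow(flag_analogs(b0, screen_proteome(gm0$proteins, refs))),
               0L)
})
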