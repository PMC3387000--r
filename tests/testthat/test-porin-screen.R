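test_that("C-terminus classifier reproduces the printed worked examples", {
  # OmpB: Y L Y L K A S V A F -> positions 3,5,7,9 = V,A,L,L
  r <- classify_cterminus("YLYLKASVAF")
  expect_true(r$terminal_is_F)
  expect_equal(r$positions[c(3, 5, 7, 9)], c("V", "A", "L", "L"))
  expect_true(r$passes_strict)
  expect_true(r$passes_relaxed)

  # Theba_0319: position 3 is K -> strict fails, relaxed passes
  r <- classify_cterminus("SLGLYFDKYF")
  expect_false(r$passes_strict)
  expect_true(r$passes_relaxed)
  expect_equal(r$odd_positions_hydrophobic, 3L)

  # no terminal phenylalanine -> fails both
  r <- classify_cterminus("YLYLKASVAK")
  expect_false(r$passes_relaxed)
  expect_match(r$reason, "phenylalanine")

  r <- classify_cterminus("MKVF")
  expect_false(r$pass)
  expect_match(r$reason, "shorter")
})

test_that("the full printed decamer suite behaves as published", {
  dec <- load_decamers()
  expect_equal(nrow(dec), 16L)
  strict <- vapply(dec$decamer,
                   function(d) classify_cterminus(d)$passes_strict,
                   logical(1))
  relaxed <- vapply(dec$decamer,
                    function(d) classify_cterminus(d)$passes_relaxed,
                    logical(1))
  expect_true(all(relaxed))
  expect_setequal(dec$protein[!strict], c("TRQ2_0459", "Theba_0319"))
})

test_that("classification depends only on the terminal decamer", {
  set.seed(13)
  for (i in 1:20) {
    tail10 <- random_seq(10)
    base <- classify_cterminus(tail10)
    with_prefix <- classify_cterminus(paste0(random_seq(sample(1:200, 1)),
                                             tail10))
    expect_equal(with_prefix$decamer, base$decamer)
    expect_equal(with_prefix$passes_strict, base$passes_strict)
    expect_equal(with_prefix$passes_relaxed, base$passes_relaxed)
  }
})

test_that("enlarging the hydrophobic set is monotone", {
  set.seed(17)
  for (i in 1:200) {
    d <- random_seq(10)
    kd <- classify_cterminus(d, hydrophobic_set = "kd_positive")
    ext <- classify_cterminus(d, hydrophobic_set = "extended")
    expect_gte(ext$odd_positions_hydrophobic, kd$odd_positions_hydrophobic)
    if (kd$passes_strict) expect_true(ext$passes_strict)
    if (kd$passes_relaxed) expect_true(ext$passes_relaxed)
    # strict pass always implies relaxed pass
    if (ext$passes_strict) expect_true(ext$passes_relaxed)
  }
})

test_that("composition score counts residues behaving like a porin", {
  bg <- SPROT_BACKGROUND
  r <- composition_porin_score(bg)
  expect_equal(r$score, 0)
  expect_false(r$porin_like)

  shifted <- bg
  shifted[PORIN_LOW_SET] <- 0
  shifted[PORIN_HIGH_SET] <- shifted[PORIN_HIGH_SET] * 2
  shifted <- shifted / sum(shifted)
  r <- composition_porin_score(shifted)
  expect_equal(r$score, 1)
  expect_true(r$porin_like)
  expect_setequal(r$low_set_ok, PORIN_LOW_SET)
  expect_setequal(r$high_set_ok, PORIN_HIGH_SET)

  badbg <- bg
  badbg["W"] <- 0
  expect_error(composition_porin_score(composition("WWWW"), background = badbg),
               "zero")
})

test_that("beta-range criterion is an interval test with tolerance", {
  expect_true(beta_range_criterion(0.25, c(0.20, 0.30)))
  expect_false(beta_range_criterion(0.10, c(0.20, 0.30), tolerance = 0.05))
  expect_true(beta_range_criterion(0.20, c(0.20, 0.30), tolerance = 0))
  expect_true(beta_range_criterion(0.34, c(0.20, 0.30), tolerance = 0.05))
  expect_error(beta_range_criterion(0.2, 0.25), "two")
  expect_error(beta_range_criterion(0.2, numeric(0)), "two")
  # summaries are accepted directly
  q <- predict_secondary_structure(strrep("V", 20))
  expect_true(beta_range_criterion(q, list(q, q)))
})

test_that("candidate calling follows the >=3-of-5 rule over all 32 vectors", {
  for (bits in 0:31) {
    v <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L, 16L)) > 0)
    cv <- criterion_vector(v[1], v[2], v[3], v[4], v[5], mw_kda = 42)
    expect_equal(cv$n_true, sum(v))
    expect_equal(cv$candidate, sum(v) >= 3)
    expect_equal(cv$strong, sum(v) == 5)
  }
})

test_that("planted porins are strong candidates and decoys are not", {
  refs <- test_references()
  cv <- evaluate_candidate(make_porin(1)$sequence, refs)
  expect_true(cv$size_ok && cv$signal_ok && cv$beta_ok &&
                cv$globular_ok && cv$cterm_ok)
  expect_true(cv$strong)

  cv <- evaluate_candidate(make_decoy(1, "disordered")$sequence, refs)
  expect_false(cv$candidate)
  # degenerate input: every criterion false, no abort
  cv <- evaluate_candidate("MK", refs)
  expect_equal(cv$n_true, 0L)
})

test_that("screening is ranked, deterministic and order-independent", {
  refs <- test_references()
  expect_equal(nrow(screen_proteome(character(0), refs)), 0L)

  pr <- make_proteome(30, 5, seed = 3)
  res1 <- screen_proteome(pr$proteins, refs)
  res2 <- screen_proteome(rev(pr$proteins), refs)
  expect_identical(res1, res2)
  # sorted by n_true desc, then |mw - 42| asc, then id
  expect_true(all(diff(res1$n_true) <= 0))
  porin_ids <- pr$truth$id[pr$truth$label == "porin"]
  expect_true(all(res1$id[1:5] %in% porin_ids))

  # explicit sort contract on a strong + failing pair
  two <- c(strong = make_porin(8)$sequence,
           dud = make_decoy(8, "disordered")$sequence)
  res <- screen_proteome(two, refs)
  expect_equal(res$id, c("strong", "dud"))
})

test_that("configuration defaults and YAML overrides are validated", {
  cfg <- screen_config()
  expect_s3_class(cfg, "screen_config")
  expect_equal(cfg$size_min, 35)
  expect_equal(cfg$size_max, 50)
  expect_equal(cfg$cterm_mode, "relaxed")
  expect_equal(cfg$hydrophobic_set, "extended")
  expect_equal(cfg$composition_threshold, 8 / 13)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("size_min: 30", "cterm_mode: strict"), yml)
  cfg <- read_screen_config(yml)
  expect_equal(cfg$size_min, 30)
  expect_equal(cfg$cterm_mode, "strict")

  writeLines("not_a_key: 1", yml)
  expect_error(read_screen_config(yml), "unknown config key")
})
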