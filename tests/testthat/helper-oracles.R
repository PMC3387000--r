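# Independent oracles and small fixture builders shared across the suite.
# These deliberately re-derive results by different means than the package
# (exhaustive enumeration, literal rule re-statement) so that agreement is
# informative.

# ---- exhaustive global alignment oracle -----------------------------------

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Maximum global alignment score by exhaustive enumeration of all alignment
# paths, with affine gaps costing open + len * extend (a gap start costs
# open + extend, each continuation costs extend). Only feasible for tiny
# sequences; that is the point.
bf_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- .blosum62[av[i], bv[j]] + rec(i + 1, j + 1, "M")
      best <- max(best, s)
    }
    if (i <= length(av)) {
      cost <- if (prev == "A") gap_extend else gap_open + gap_extend
      best <- max(best, rec(i + 1, j, "A") - cost)
    }
    if (j <= length(bv)) {
      cost <- if (prev == "B") gap_extend else gap_open + gap_extend
      best <- max(best, rec(i, j + 1, "B") - cost)
    }
    best
  }
  rec(1, 1, "M")
}

# ---- literal re-statement of the C-terminus rule --------------------------

# "terminal phenylalanine, and hydrophobic residues at positions 1, 3, 5, 7
# and 9 counted from the C-terminus"; strict requires all of 3,5,7,9,
# relaxed at least 3 of them.
bf_cterm <- function(seq, set, mode) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 10) return(FALSE)
  last <- ch[n]
  odd_res <- c(ch[n - 2], ch[n - 4], ch[n - 6], ch[n - 8])
  k <- sum(odd_res %in% set)
  if (mode == "strict") last == "F" && k == 4 else last == "F" && k >= 3
}

# ---- random sequence helpers ----------------------------------------------

random_seq <- function(n, alphabet = togascreen::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reference porin set used wherever the screen needs references.
test_references <- function() {
  refs <- vapply(9001:9005, function(s) make_porin(s)$sequence, character(1))
  names(refs) <- paste0("ref_", 9001:9005)
  refs
}

# The printed C-terminal decamers of known porins, OmpB homologs and the
# putative analogs (shipped as package data).
load_decamers <- function() {
  path <- system.file("extdata", "known_porin_decamers.tsv",
                      package = "togascreen")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
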