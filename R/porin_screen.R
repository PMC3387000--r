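# The core inference: C-terminal anchoring-signature classification,
# composition-bias scoring, the beta-range criterion, and the >=3-of-5
# candidate caller.

#' Screening configuration
#'
#' Bundles every tunable threshold of the porin screen with its default.
#' Defaults: candidate size window 35-50 kDa centred on the ~42 kDa porin
#' monomer; relaxed C-terminus mode with the extended hydrophobic set;
#' beta-range tolerance 0.05; composition-bias threshold 8/13; the
#' signal-peptide and globularity defaults of their respective functions.
#'
#' @param size_min,size_max Candidate molecular-weight window in kDa.
#' @param size_center Reference monomer mass (kDa) used only for ranking
#'   tie-breaks.
#' @param cterm_mode `"relaxed"` (terminal F and >= 3 hydrophobic odd
#'   positions) or `"strict"` (all 4).
#' @param hydrophobic_set `"extended"` or `"kd_positive"`.
#' @param beta_tolerance Slack around the reference beta-content range.
#' @param composition_threshold Minimum composition-bias score for a
#'   porin-like call.
#' @param h_kd_min,site_min,site_max Signal-peptide rule thresholds.
#' @param smooth_window,min_len,coverage_min Globularity detector settings.
#' @param allow_x Admit `X` residues at parse time.
#' @return A named list of class `screen_config`.
#' @export
screen_config <- function(size_min = 35, size_max = 50, size_center = 42,
                          cterm_mode = c("relaxed", "strict"),
                          hydrophobic_set = c("extended", "kd_positive"),
                          beta_tolerance = 0.05,
                          composition_threshold = 8 / 13,
                          h_kd_min = 1.6, site_min = 10L, site_max = 45L,
                          smooth_window = 15L, min_len = 40L,
                          coverage_min = 0.5, allow_x = FALSE) {
  cfg <- list(
    size_min = size_min, size_max = size_max, size_center = size_center,
    cterm_mode = match.arg(cterm_mode),
    hydrophobic_set = match.arg(hydrophobic_set),
    beta_tolerance = beta_tolerance,
    composition_threshold = composition_threshold,
    h_kd_min = h_kd_min, site_min = site_min, site_max = site_max,
    smooth_window = smooth_window, min_len = min_len,
    coverage_min = coverage_min, allow_x = allow_x
  )
  stopifnot(cfg$size_min > 0, cfg$size_max > cfg$size_min,
            cfg$beta_tolerance >= 0,
            cfg$composition_threshold >= 0, cfg$composition_threshold <= 1)
  class(cfg) <- "screen_config"
  cfg
}

#' Read a screening configuration from YAML
#'
#' Reads a YAML file of threshold overrides and merges it over the defaults
#' of [screen_config()]. Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `screen_config` list.
#' @export
read_screen_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  known <- names(formals(screen_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(screen_config, overrides)
}

#' Classify a protein C-terminus for the porin anchoring signature
#'
#' Examines the last ten residues (the terminal decamer; position 1 is the
#' C-terminal residue, positions ascend toward the N-terminus). The porin
#' anchoring signature is a terminal phenylalanine plus hydrophobic residues
#' at the alternating positions 3, 5, 7 and 9. Two pass rules are reported:
#' strict (terminal F and all four odd positions hydrophobic) and relaxed
#' (terminal F and at least three of the four).
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @param hydrophobic_set `"extended"` (default) or `"kd_positive"`; see
#'   [hydrophobic_set()].
#' @param mode Which rule decides the `pass` field: `"relaxed"` (default) or
#'   `"strict"`.
#' @return A list with `decamer` (as a string, N-to-C as conventionally
#'   printed), `positions` (residues indexed 1..10 from the C-terminus),
#'   `terminal_is_F`, `hydrophobic_mask` (positions 1..10),
#'   `odd_positions_hydrophobic` (count over \{3,5,7,9\}), `passes_strict`,
#'   `passes_relaxed`, `pass` (per `mode`) and `reason` for failures.
#' @examples
#' classify_cterminus("MKAYLYLKASVAF")$passes_strict  # TRUE
#' @export
classify_cterminus <- function(seq,
                               hydrophobic_set = c("extended", "kd_positive"),
                               mode = c("relaxed", "strict")) {
  hydrophobic_set <- match.arg(hydrophobic_set)
  mode <- match.arg(mode)
  seq <- as.character(seq)[1]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 10L) {
    return(list(decamer = NA_character_, positions = NULL,
                terminal_is_F = FALSE,
                hydrophobic_mask = rep(FALSE, 10L),
                odd_positions_hydrophobic = 0L,
                passes_strict = FALSE, passes_relaxed = FALSE,
                pass = FALSE, reason = "sequence shorter than 10 residues"))
  }
  decamer_nc <- chars[(n - 9L):n]           # N -> C, as printed
  positions <- rev(decamer_nc)              # position 1 = C-terminal residue
  mask <- is_hydrophobic(positions, hydrophobic_set)
  odd <- c(3L, 5L, 7L, 9L)
  n_odd <- sum(mask[odd])
  terminal_is_F <- positions[1] == "F"
  strict <- terminal_is_F && n_odd == 4L
  relaxed <- terminal_is_F && n_odd >= 3L
  pass <- if (mode == "strict") strict else relaxed
  reason <- if (pass) {
    NA_character_
  } else if (!terminal_is_F) {
    "no terminal phenylalanine"
  } else {
    "too few hydrophobic residues at positions 3,5,7,9"
  }
  list(decamer = paste(decamer_nc, collapse = ""), positions = positions,
       terminal_is_F = terminal_is_F, hydrophobic_mask = mask,
       odd_positions_hydrophobic = n_odd,
       passes_strict = strict, passes_relaxed = relaxed,
       pass = pass, reason = reason)
}

#' Porin composition-bias score
#'
#' Scores how closely an amino-acid composition follows the porin bias: low
#' abundance (strictly below background) of the eight characteristically
#' depleted residues ([PORIN_LOW_SET]) and high abundance (strictly above
#' background) of the five characteristically enriched residues
#' ([PORIN_HIGH_SET]). The score is the fraction of the 13 residues behaving
#' as expected.
#'
#' @param profile A composition as returned by [composition()], or a named
#'   fraction vector over [AA_ALPHABET].
#' @param background Background composition (named fraction vector); default
#'   [SPROT_BACKGROUND].
#' @param threshold Minimum score for a `porin_like` call (default 8/13).
#' @return A list with `low_set_ok`, `high_set_ok` (residues behaving as
#'   expected), `score` in \[0, 1\] and `porin_like`.
#' @export
composition_porin_score <- function(profile, background = SPROT_BACKGROUND,
                                    threshold = 8 / 13) {
  frac <- if (is.list(profile)) profile$fraction else profile
  if (is.null(names(frac)) || !all(AA_ALPHABET %in% names(frac))) {
    stop("profile must be named over the canonical alphabet", call. = FALSE)
  }
  if (!all(AA_ALPHABET %in% names(background))) {
    stop("background must cover the canonical alphabet", call. = FALSE)
  }
  present <- AA_ALPHABET[frac[AA_ALPHABET] > 0]
  zero_bg <- present[background[present] == 0]
  if (length(zero_bg)) {
    stop("background fraction is zero for residue(s) present in the query: ",
         paste(zero_bg, collapse = ", "), call. = FALSE)
  }
  low_ok <- PORIN_LOW_SET[frac[PORIN_LOW_SET] < background[PORIN_LOW_SET]]
  high_ok <- PORIN_HIGH_SET[frac[PORIN_HIGH_SET] > background[PORIN_HIGH_SET]]
  score <- (length(low_ok) + length(high_ok)) / 13
  list(low_set_ok = low_ok, high_set_ok = high_ok,
       score = score, porin_like = score >= threshold)
}

#' Beta-strand content range criterion
#'
#' A candidate's beta-strand content passes if it falls within the range
#' spanned by reference porins, widened by a tolerance on each side. Query
#' and references must come from the same predictor, so the comparison is
#' self-consistent; printed percentages from external tools are never the
#' comparison surface.
#'
#' @param query A secondary-structure summary (from
#'   [predict_secondary_structure()]) or a bare `frac_E` number.
#' @param references A list of summaries or numeric vector of reference
#'   `frac_E` values; at least two are required.
#' @param tolerance Slack added below the minimum and above the maximum
#'   (default 0.05).
#' @return `TRUE` or `FALSE`.
#' @export
beta_range_criterion <- function(query, references, tolerance = 0.05) {
  q <- if (is.list(query)) query$frac_E else query
  refs <- if (is.list(references)) {
    vapply(references, function(r) if (is.list(r)) r$frac_E else r, numeric(1))
  } else {
    as.numeric(references)
  }
  if (length(refs) < 2L) {
    stop("at least two reference beta contents are required", call. = FALSE)
  }
  stopifnot(tolerance >= 0)
  q >= min(refs) - tolerance && q <= max(refs) + tolerance
}

#' Reference beta-strand contents
#'
#' Convenience: run [predict_secondary_structure()] over a reference protein
#' set and return the `frac_E` values, named by record id.
#'
#' @param references An `AAStringSet` or (named) character vector.
#' @return Named numeric vector of beta-strand fractions.
#' @export
reference_beta_fractions <- function(references) {
  seqs <- protein_seqs(references)
  vapply(seqs, function(s) predict_secondary_structure(s)$frac_E, numeric(1))
}

#' Assemble a criterion vector
#'
#' Combines the five boolean screening criteria into the candidate call:
#' a protein is a candidate when at least three criteria hold, and a strong
#' candidate when all five hold.
#'
#' @param size_ok,signal_ok,beta_ok,globular_ok,cterm_ok Logical criteria.
#' @param mw_kda Molecular weight in kDa (carried along for ranking).
#' @return A list with the criteria, `mw_kda`, `n_true`, `candidate` and
#'   `strong`.
#' @export
criterion_vector <- function(size_ok, signal_ok, beta_ok, globular_ok,
                             cterm_ok, mw_kda = NA_real_) {
  crit <- c(size_ok = isTRUE(size_ok), signal_ok = isTRUE(signal_ok),
            beta_ok = isTRUE(beta_ok), globular_ok = isTRUE(globular_ok),
            cterm_ok = isTRUE(cterm_ok))
  n_true <- sum(crit)
  c(as.list(crit),
    list(mw_kda = mw_kda, n_true = n_true,
         candidate = n_true >= 3L, strong = n_true == 5L))
}

# A component failure on a degenerate sequence yields a FALSE criterion,
# never an abort: the screen must run proteome-wide.
.safe_false <- function(expr) {
  tryCatch(isTRUE(expr), error = function(e) FALSE)
}

#' Evaluate one protein against the five porin criteria
#'
#' Applies the five sequence-derived porin criteria to one protein:
#' molecular size within the configured window, a detectable Sec signal
#' peptide, beta-strand content within the reference range, a globular fold,
#' and the C-terminal anchoring signature. Component failures on degenerate
#' sequences make that criterion `FALSE` rather than aborting.
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @param references Reference porins: an `AAStringSet`/character vector of
#'   sequences, or a precomputed numeric vector of reference `frac_E` values
#'   (see [reference_beta_fractions()]).
#' @param config A [screen_config()].
#' @return A criterion vector (see [criterion_vector()]) with `frac_E` and
#'   `composition_score` attached.
#' @export
evaluate_candidate <- function(seq, references, config = screen_config()) {
  seq <- as.character(seq)[1]
  ref_fracs <- if (is.numeric(references)) {
    references
  } else {
    reference_beta_fractions(references)
  }
  mw_kda <- tryCatch(compute_mw(seq)$mw_kda, error = function(e) NA_real_)
  size_ok <- !is.na(mw_kda) &&
    mw_kda >= config$size_min && mw_kda <= config$size_max
  signal_ok <- .safe_false(
    detect_signal_peptide(seq, h_kd_min = config$h_kd_min,
                          site_min = config$site_min,
                          site_max = config$site_max)$present)
  ss <- tryCatch(predict_secondary_structure(seq), error = function(e) NULL)
  frac_E <- if (is.null(ss)) NA_real_ else ss$frac_E
  beta_ok <- !is.null(ss) && .safe_false(
    beta_range_criterion(ss, ref_fracs, tolerance = config$beta_tolerance))
  globular_ok <- .safe_false(
    assess_globularity(seq, smooth_window = config$smooth_window,
                       min_len = config$min_len,
                       coverage_min = config$coverage_min)$globular)
  cterm_ok <- .safe_false(
    classify_cterminus(seq, hydrophobic_set = config$hydrophobic_set,
                       mode = config$cterm_mode)$pass)
  comp_score <- tryCatch(
    composition_porin_score(composition(seq),
                            threshold = config$composition_threshold)$score,
    error = function(e) NA_real_)
  out <- criterion_vector(size_ok, signal_ok, beta_ok, globular_ok, cterm_ok,
                          mw_kda = mw_kda)
  out$frac_E <- frac_E
  out$composition_score <- comp_score
  out
}

#' Screen a proteome for porin candidates
#'
#' Evaluates every protein against the five criteria and returns a ranked
#' table: candidates with more criteria first, ties broken by distance from
#' the reference monomer mass (`size_center`, default 42 kDa) and then by id.
#' The ranking is deterministic and order-independent.
#'
#' @param proteins An `AAStringSet` or named character vector of sequences.
#' @param references Reference porins (sequences or precomputed `frac_E`
#'   values).
#' @param config A [screen_config()].
#' @return A `data.frame` with one row per protein: `id`, `mw_kda`,
#'   `size_ok`, `signal_ok`, `beta_ok`, `globular_ok`, `cterm_ok`, `frac_E`,
#'   `composition_score`, `n_true`, `candidate`, `strong`.
#' @export
screen_proteome <- function(proteins, references, config = screen_config()) {
  seqs <- protein_seqs(proteins)
  ref_fracs <- if (is.numeric(references)) {
    references
  } else {
    reference_beta_fractions(references)
  }
  empty <- data.frame(id = character(0), mw_kda = numeric(0),
                      size_ok = logical(0), signal_ok = logical(0),
                      beta_ok = logical(0), globular_ok = logical(0),
                      cterm_ok = logical(0), frac_E = numeric(0),
                      composition_score = numeric(0), n_true = integer(0),
                      candidate = logical(0), strong = logical(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  rows <- lapply(seq_along(seqs), function(i) {
    cv <- evaluate_candidate(seqs[[i]], ref_fracs, config)
    data.frame(id = names(seqs)[i], mw_kda = cv$mw_kda,
               size_ok = cv$size_ok, signal_ok = cv$signal_ok,
               beta_ok = cv$beta_ok, globular_ok = cv$globular_ok,
               cterm_ok = cv$cterm_ok, frac_E = cv$frac_E,
               composition_score = cv$composition_score,
               n_true = cv$n_true, candidate = cv$candidate,
               strong = cv$strong, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dist <- abs(out$mw_kda - config$size_center)
  dist[is.na(dist)] <- Inf
  ord <- order(-out$n_true, dist, out$id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
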