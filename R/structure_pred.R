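# Internal heuristic structure predictors backing three screening criteria:
# beta-strand content (Chou-Fasman), Sec signal peptide (rule-based), and
# globularity (disorder-propensity running sum).

# Propensity lookup with X (if admitted) scored as a breaker (0).
.propensity <- function(chars, table) {
  p <- unname(table[chars])
  p[is.na(p)] <- 0
  p
}

# Maximal runs of TRUE in a logical vector, as a 2-column matrix (start, end).
.true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Grow a nucleated region [i, j] outward while the mean propensity of the
# 4-residue window crossing the boundary stays >= 100 (classic Chou-Fasman
# extension rule).
.extend_region <- function(p, i, j) {
  n <- length(p)
  while (j < n && mean(p[(j - 2):(j + 1)]) >= 100) j <- j + 1L
  while (i > 1 && mean(p[i:(i + 3)]) >= 100) i <- i - 1L
  c(i, j)
}

# Residue mask of predicted regions for one state. Nucleation: at least
# `need` of `win` consecutive residues with propensity > 100; then extension.
.cf_state_mask <- function(p, win, need) {
  n <- length(p)
  mask <- logical(n)
  if (n < win) return(mask)
  gt <- as.integer(p > 100)
  cs <- cumsum(c(0L, gt))
  counts <- cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]
  for (i in which(counts >= need)) {
    j <- i + win - 1L
    if (mask[i] && mask[j]) next  # already inside an accepted region
    ij <- .extend_region(p, i, j)
    mask[ij[1]:ij[2]] <- TRUE
  }
  mask
}

#' Chou-Fasman secondary-structure prediction
#'
#' Single-sequence secondary-structure assignment by the classic Chou-Fasman
#' procedure: helices nucleate where 4 of 6 consecutive residues have helix
#' propensity > 100 and extend while the 4-residue boundary window keeps a
#' mean propensity >= 100; strands nucleate where 3 of 5 consecutive residues
#' have strand propensity > 100, with the same extension rule. Residues
#' claimed by both states are resolved segment-wise to the state with the
#' higher summed propensity (ties favour strand). Everything else is coil.
#' The reported beta-strand content is `frac_E`.
#'
#' Sequences shorter than 6 residues cannot nucleate either state; they are
#' returned as all-coil with `too_short = TRUE` rather than as an error, so
#' that proteome-wide screens tolerate short decoys.
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @return A list with `states` (per-residue labels in H/E/C), `frac_H`,
#'   `frac_E`, `frac_C`, `method` and `too_short`.
#' @export
predict_secondary_structure <- function(seq) {
  seq <- as.character(seq)[1]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  pa <- .propensity(chars, CHOU_FASMAN_HELIX)
  pb <- .propensity(chars, CHOU_FASMAN_STRAND)
  states <- rep("C", n)
  too_short <- n < 6L
  if (!too_short) {
    hmask <- .cf_state_mask(pa, win = 6L, need = 4L)
    emask <- .cf_state_mask(pb, win = 5L, need = 3L)
    states[hmask] <- "H"
    states[emask] <- "E"
    both <- hmask & emask
    if (any(both)) {
      runs <- .true_runs(both)
      for (k in seq_len(nrow(runs))) {
        idx <- runs[k, "start"]:runs[k, "end"]
        states[idx] <- if (sum(pa[idx]) > sum(pb[idx])) "H" else "E"
      }
    }
  }
  list(
    states = states,
    frac_H = mean(states == "H"),
    frac_E = mean(states == "E"),
    frac_C = mean(states == "C"),
    method = "chou-fasman",
    too_short = too_short
  )
}

#' Rule-based Sec signal-peptide detection
#'
#' Detects a classical Sec export signal from three rules applied to the
#' first 45 residues:
#' \itemize{
#'   \item n-region: at least one K or R within residues 1-7;
#'   \item h-region: a stretch of >= 7 consecutive residues within residues
#'     4-25 with mean Kyte-Doolittle hydropathy >= `h_kd_min`; the region
#'     starts at the first qualifying 7-residue window and extends
#'     residue-by-residue while hydropathy stays >= `h_kd_min` (capped at
#'     residue 25);
#'   \item c-region: a cleavage site `site_min`-`site_max` residues in that
#'     satisfies the (-3,-1) small-residue rule (residue at -1 in
#'     \{A,G,S,C,T\}, at -3 in \{A,G,S,C,T,V,I,L\}) and lies at least 2
#'     residues after the h-region ends. The first qualifying site is
#'     reported as `cleavage_after`.
#' }
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @param h_kd_min Minimum mean hydropathy of the h-region window
#'   (default 1.6).
#' @param site_min,site_max 1-based bounds on the cleavage position
#'   (defaults 10 and 45).
#' @return A list with `present`, `cleavage_after` (1-based index of the last
#'   signal residue, or `NA`), `h_region` (integer start/end, or `NULL`),
#'   `score` (mean h-region hydropathy, 0 if absent) and `too_short`
#'   (sequences under 30 residues are never called).
#' @export
detect_signal_peptide <- function(seq, h_kd_min = 1.6,
                                  site_min = 10L, site_max = 45L) {
  seq <- as.character(seq)[1]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  none <- list(present = FALSE, cleavage_after = NA_integer_,
               h_region = NULL, score = 0, too_short = FALSE)
  if (n < 30L) {
    none$too_short <- TRUE
    return(none)
  }
  # detection only looks at the N-terminal 45 residues
  m <- min(n, 45L)
  chars <- chars[1:m]
  kd <- unname(KYTE_DOOLITTLE[chars])
  kd[is.na(kd)] <- 0

  # n-region: positive charge near the start
  if (!any(chars[1:7] %in% c("K", "R"))) return(none)

  # h-region: first qualifying 7-window in residues 4..25, then extend
  h_last <- min(25L, m)
  h_start <- NA_integer_
  for (i in 4:(h_last - 6L)) {
    if (mean(kd[i:(i + 6L)]) >= h_kd_min) {
      h_start <- i
      break
    }
  }
  if (is.na(h_start)) return(none)
  h_end <- h_start + 6L
  while (h_end < h_last && kd[h_end + 1L] >= h_kd_min) h_end <- h_end + 1L

  # c-region: first (-3,-1)-conforming site downstream of the h-region
  minus1 <- c("A", "G", "S", "C", "T")
  minus3 <- c("A", "G", "S", "C", "T", "V", "I", "L")
  lo <- max(site_min, h_end + 2L)
  hi <- min(site_max, m, n - 1L)  # the mature protein must be non-empty
  if (lo <= hi) {
    for (cpos in lo:hi) {
      if (chars[cpos] %in% minus1 && chars[cpos - 2L] %in% minus3) {
        return(list(present = TRUE, cleavage_after = cpos,
                    h_region = c(start = h_start, end = h_end),
                    score = mean(kd[h_start:h_end]), too_short = FALSE))
      }
    }
  }
  none
}

#' Globularity assessment by disorder-propensity running sum
#'
#' Computes the running sum of Russell-Linding disorder propensities,
#' S_i = sum_\{j<=i\} (p(aa_j) - center), smooths it with a centred moving
#' average, and reports maximal downhill (non-increasing) stretches of the
#' smoothed curve of at least `min_len` residues as globular domains.
#' Order-promoting (hydrophobic-core) sequences drive the curve downhill;
#' disorder-promoting compositions drive it uphill.
#'
#' The propensity scale is already a difference measure (random-coil minus
#' regular-structure preference), so `center` defaults to 0: an ordinary
#' folded protein drifts mildly downhill and reads as globular, while
#' genuinely disorder-biased compositions climb. This matches the behaviour
#' of running-sum globularity tools on real porins, which are called
#' globular despite their substantial loop content.
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @param smooth_window Centred moving-average window (default 15; edges use
#'   shrunken windows).
#' @param min_len Minimum domain length in residues (default 40).
#' @param coverage_min Fraction of the sequence that must lie inside domains
#'   for a globular call (default 0.5).
#' @param center Constant subtracted from every residue propensity before
#'   summing (default 0; set to `mean(DISORDER_PROPENSITY)` for a
#'   table-centred sum).
#' @return A list with `globular`, `domains` (matrix of start/end rows,
#'   possibly empty), `coverage` and the smoothed curve `profile`.
#' @export
assess_globularity <- function(seq, smooth_window = 15L, min_len = 40L,
                               coverage_min = 0.5, center = 0) {
  seq <- as.character(seq)[1]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- list(globular = FALSE,
                domains = cbind(start = integer(0), end = integer(0)),
                coverage = 0, profile = numeric(0))
  if (n == 0L) return(empty)
  p <- .propensity(chars, DISORDER_PROPENSITY)
  p[!chars %in% AA_ALPHABET] <- 0
  s <- cumsum(p - center)
  sm <- .moving_average(s, smooth_window)
  empty$profile <- sm
  if (n < 2L) return(empty)
  downhill <- diff(sm) <= 0
  runs <- .true_runs(downhill)
  if (nrow(runs) == 0L) return(empty)
  # a run of k non-increasing steps spans k + 1 residues
  lens <- runs[, "end"] - runs[, "start"] + 2L
  keep <- lens >= min_len
  domains <- cbind(start = runs[keep, "start"],
                   end = runs[keep, "end"] + 1L)
  coverage <- if (nrow(domains)) {
    sum(domains[, "end"] - domains[, "start"] + 1L) / n
  } else 0
  list(globular = coverage >= coverage_min, domains = domains,
       coverage = coverage, profile = sm)
}

# Centred moving average with shrinking windows at the edges (output has the
# input's length).
.moving_average <- function(x, window) {
  n <- length(x)
  half <- (as.integer(window) - 1L) %/% 2L
  if (n == 0L || half == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
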