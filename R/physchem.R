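# Sequence-intrinsic physicochemical calculations: molecular weight,
# composition, Kyte-Doolittle hydropathy.

# Split a sequence into residues, optionally dropping X (the only tolerated
# non-canonical code; every other character must have been rejected at parse).
split_residues <- function(seq, drop_x = TRUE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (drop_x) chars <- chars[chars != "X"]
  chars
}

#' Average molecular weight of a protein
#'
#' ProtParam-style average (not monoisotopic) molecular weight: the sum of
#' the Expasy average residue masses plus one water. `X` residues, if
#' admitted at parse time, are excluded.
#'
#' @param seq Protein sequence (character scalar) or a length-1
#'   `AAStringSet`.
#' @return A list with `average_mass` (Da), `mw_kda` (kDa) and `n_residues`.
#' @examples
#' compute_mw("G")$average_mass   # 75.07 Da
#' compute_mw("GG")$average_mass  # 132.12 Da
#' @export
compute_mw <- function(seq) {
  seq <- as.character(seq)[1]
  chars <- split_residues(seq)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  unknown <- setdiff(unique(chars), AA_ALPHABET)
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mass <- sum(AA_AVG_MASS[chars]) + WATER_MASS
  list(average_mass = mass, mw_kda = mass / 1000, n_residues = length(chars))
}

#' Amino-acid composition of a protein
#'
#' Per-residue counts and fractions over all counted residues (the full
#' canonical alphabet; `X` is excluded from the denominator).
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @return A list with `counts` and `fraction`, both named numeric vectors
#'   over [AA_ALPHABET]; fractions sum to 1.
#' @export
composition <- function(seq) {
  seq <- as.character(seq)[1]
  chars <- split_residues(seq)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  list(counts = counts, fraction = counts / sum(counts))
}

#' Kyte-Doolittle hydropathy profile
#'
#' Per-residue Kyte-Doolittle hydropathy values and their sliding-window
#' means. For a sequence of length n and window w (odd), the windowed profile
#' has n - w + 1 values; sequences shorter than the window yield an empty
#' windowed profile.
#'
#' @param seq Protein sequence (character scalar) or length-1 `AAStringSet`.
#' @param window Odd positive integer window size (default 9). `X` residues
#'   are scored 0 (non-hydrophobic).
#' @return A list with `per_residue`, `windowed` and `window`.
#' @export
hydropathy_profile <- function(seq, window = 9L) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  window <- as.integer(window)
  seq <- as.character(seq)[1]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  per <- unname(KYTE_DOOLITTLE[chars])
  per[is.na(per)] <- 0  # X (if admitted) scores as non-hydrophobic
  n <- length(per)
  if (n >= window) {
    cs <- cumsum(c(0, per))
    win <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  } else {
    win <- numeric(0)
  }
  list(per_residue = per, windowed = win, window = window)
}

#' Is a residue hydrophobic?
#'
#' Membership of a residue in one of the two hydrophobic sets used by the
#' C-terminal anchoring signature: `kd_positive` (positive Kyte-Doolittle
#' value: A, C, F, I, L, M, V) or `extended` (additionally W and Y).
#'
#' @param residue One-letter residue code (vectorised).
#' @param set_name `"extended"` (default) or `"kd_positive"`.
#' @return Logical vector.
#' @examples
#' is_hydrophobic("Y", "kd_positive")  # FALSE
#' is_hydrophobic("Y", "extended")     # TRUE
#' @export
is_hydrophobic <- function(residue, set_name = c("extended", "kd_positive")) {
  set_name <- match.arg(set_name)
  residue <- toupper(residue)
  bad <- setdiff(unique(residue), c(AA_ALPHABET, "X"))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  residue %in% .HYDROPHOBIC_SETS[[set_name]]
}
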