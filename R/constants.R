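#' Canonical amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order.
#' All per-residue tables in the package are named by this alphabet.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Average residue masses (Da)
#'
#' Average isotopic masses of amino-acid residues (i.e. the monomer mass less
#' one water), as tabulated by Expasy and used by ProtParam-style molecular
#' weight calculations. The mass of a peptide is the sum of its residue masses
#' plus one water ([WATER_MASS]).
#'
#' @format Named numeric vector over [AA_ALPHABET], daltons.
#' @seealso [compute_mw()]
#' @export
AA_AVG_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)

#' Mass of one water molecule (Da)
#'
#' Average isotopic mass of H2O, added once per peptide chain.
#' @export
WATER_MASS <- 18.01524

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values from the Kyte-Doolittle scale. Positive
#' values are hydrophobic. Used for sliding-window hydropathy profiles and
#' for the signal-peptide h-region rule.
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @seealso [hydropathy_profile()], [is_hydrophobic()]
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Chou-Fasman helix propensities
#'
#' Classic Chou-Fasman alpha-helix conformational propensities, on the
#' conventional x100 scale (values > 100 favour helix).
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @seealso [predict_secondary_structure()]
#' @export
CHOU_FASMAN_HELIX <- c(
  A = 142, C =  70, D = 101, E = 151, F = 113,
  G =  57, H = 100, I = 108, K = 116, L = 121,
  M = 145, N =  67, P =  57, Q = 111, R =  98,
  S =  77, T =  83, V = 106, W = 108, Y =  69
)

#' Chou-Fasman strand propensities
#'
#' Classic Chou-Fasman beta-strand conformational propensities, x100 scale
#' (values > 100 favour strand).
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @seealso [predict_secondary_structure()]
#' @export
CHOU_FASMAN_STRAND <- c(
  A =  83, C = 119, D =  54, E =  37, F = 138,
  G =  75, H =  87, I = 160, K =  74, L = 130,
  M = 105, N =  89, P =  55, Q = 110, R =  93,
  S =  75, T = 119, V = 170, W = 137, Y = 147
)

#' Russell-Linding disorder propensities
#'
#' Per-residue disorder propensities (random-coil versus regular secondary
#' structure preference). Positive values favour disorder; negative values
#' favour ordered, globular structure. Drives the running-sum globularity
#' detector.
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @seealso [assess_globularity()]
#' @export
DISORDER_PROPENSITY <- c(
  A = -0.261538, C = -0.015151, D =  0.227676, E = -0.204684, F = -0.225572,
  G =  0.433225, H = -0.001217, I = -0.422234, K = -0.100092, L = -0.337933,
  M = -0.225905, N =  0.229885, P =  0.552338, Q = -0.187424, R = -0.176516,
  S =  0.142595, T =  0.008877, V = -0.386174, W = -0.243375, Y = -0.207510
)

#' Swiss-Prot average amino-acid composition
#'
#' Background amino-acid frequencies from the UniProtKB/Swiss-Prot release
#' statistics, renormalised to sum to exactly 1. Default background for the
#' porin composition-bias score.
#'
#' @format Named numeric vector over [AA_ALPHABET], fractions summing to 1.
#' @seealso [composition_porin_score()]
#' @export
SPROT_BACKGROUND <- local({
  pct <- c(
    A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
    G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
    M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
  )
  pct / sum(pct)
})

#' Residues typically depleted in porins
#'
#' The eight residues whose abundance is characteristically low in
#' beta-barrel porins relative to a generic protein background.
#' @export
PORIN_LOW_SET <- c("R", "C", "E", "H", "I", "M", "P", "W")

#' Residues typically enriched in porins
#'
#' The five residues whose abundance is characteristically high in
#' beta-barrel porins relative to a generic protein background.
#' @export
PORIN_HIGH_SET <- c("A", "G", "N", "D", "L")

# Hydrophobic residue sets used by the C-terminal anchoring signature.
# kd_positive: residues with positive Kyte-Doolittle hydropathy.
# extended: kd_positive plus the aromatics W and Y, the set consistent with
# how membrane-facing residues of porin C-termini are conventionally marked.
.HYDROPHOBIC_SETS <- list(
  kd_positive = c("A", "C", "F", "I", "L", "M", "V"),
  extended    = c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
)

#' Hydrophobic residue set by name
#'
#' @param set_name `"kd_positive"` (residues with Kyte-Doolittle value > 0)
#'   or `"extended"` (additionally W and Y).
#' @return Character vector of one-letter residue codes.
#' @seealso [is_hydrophobic()], [classify_cterminus()]
#' @export
hydrophobic_set <- function(set_name = c("extended", "kd_positive")) {
  set_name <- match.arg(set_name)
  .HYDROPHOBIC_SETS[[set_name]]
}
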