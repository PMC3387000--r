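#' C-terminal decamers of known porins and Thermotogales OmpB proteins
#'
#' The published C-terminal decamers (printed N-to-C) of four classic
#' enterobacterial reference porins, ten Thermotogales OmpB homologs and
#' the two putative syntenic analog porins, shipped as package data. These
#' are the worked examples for the C-terminal anchoring-signature
#' classifier: every decamer passes the relaxed rule, and under the strict
#' rule exactly TRQ2_0459 and Theba_0319 fail.
#'
#' @return A data.frame with columns `protein`, `group`
#'   (`reference_porin`, `ompB_homolog`, `putative_analog`) and `decamer`.
#' @seealso [classify_cterminus()]
#' @export
known_porin_decamers <- function() {
  path <- system.file("extdata", "known_porin_decamers.tsv",
                      package = "togascreen", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
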