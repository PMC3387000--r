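#' Read a protein FASTA file
#'
#' Reads a multi-record FASTA file into an [Biostrings::AAStringSet].
#' Sequences are uppercased, line wrapping is normalised away, and every
#' residue is validated against the 20 canonical one-letter codes. Record ids
#' (the first whitespace-delimited token of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @param allow_x If `TRUE`, the ambiguity code `X` is accepted; per-residue
#'   statistics elsewhere in the package exclude `X` and treat it as
#'   non-hydrophobic. Default `FALSE` (strict canonical alphabet).
#' @return An `AAStringSet`; `names()` hold the full headers. Use
#'   [protein_ids()] for the id tokens.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a toy", "mkf", "vl"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    validate_sequence(seqs[[i]], id = ids[[i]], allow_x = allow_x)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- headers
  out
}

#' Write protein records as FASTA
#'
#' @param x An `AAStringSet` or named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_aastringset(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Validate a protein sequence
#'
#' Checks that a sequence is non-empty, uppercase and drawn from the 20
#' canonical one-letter codes (plus `X` when `allow_x = TRUE`). Errors name
#' the offending residue and its 1-based position.
#'
#' @param seq Character scalar sequence.
#' @param id Record id used in error messages.
#' @param allow_x Accept the ambiguity code `X`.
#' @return Invisibly, the validated (uppercased) sequence.
#' @export
validate_sequence <- function(seq, id = "<sequence>", allow_x = FALSE) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  allowed <- AA_ALPHABET
  if (allow_x) allowed <- c(allowed, "X")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop("record '", id, "': illegal residue '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(seq)
}

#' Record ids of a protein set
#'
#' The id of a record is the first whitespace-delimited token of its FASTA
#' header.
#'
#' @param x An `AAStringSet` or named character vector.
#' @return Character vector of ids.
#' @export
protein_ids <- function(x) {
  if (length(x) == 0L) return(character(0))
  headers <- names(x)
  if (is.null(headers)) stop("protein set has no names/headers", call. = FALSE)
  vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
}

#' Protein set as a named character vector of sequences
#'
#' @param x An `AAStringSet` or character vector of sequences.
#' @return Named character vector; names are the record ids.
#' @export
protein_seqs <- function(x) {
  s <- as.character(x)
  names(s) <- protein_ids(x)
  s
}

# Coerce a character vector (or AAStringSet) to AAStringSet, keeping names.
as_aastringset <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  out <- Biostrings::AAStringSet(as.character(x))
  names(out) <- names(x)
  out
}

#' Read a per-genome gene table
#'
#' Reads a tab-delimited table of gene loci with columns `genome_id`,
#' `locus_tag`, `ordinal`, `strand`, `family`. Ordinals are 0-based positions
#' along the replicon; `family` may be empty. The returned table is grouped
#' by genome and sorted by ordinal within each genome.
#'
#' @param path Path to a tab-delimited file with the header above.
#' @return A `data.frame` with the five columns; `ordinal` is integer,
#'   `strand` one of `"+"`/`"-"`, `family` character (possibly `""`).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) {
    stop("gene table does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", comment.char = "")
  need <- c("genome_id", "locus_tag", "ordinal", "strand", "family")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("gene table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  df$ordinal <- suppressWarnings(as.integer(df$ordinal))
  validate_gene_table(df)
}

#' Validate (and normalise) a gene table
#'
#' Enforces the gene-table invariants: unique `(genome_id, locus_tag)` pairs,
#' unique ordinals within a genome, strand in `{+, -}`, non-negative integer
#' ordinals. Returns the table sorted by genome then ordinal.
#'
#' @param df A data.frame with columns `genome_id`, `locus_tag`, `ordinal`,
#'   `strand`, `family`.
#' @return The validated, sorted data.frame.
#' @export
validate_gene_table <- function(df) {
  # tolerate the typographic minus occasionally found in curated tables
  df$strand <- gsub("−", "-", df$strand)
  if (anyNA(df$ordinal) || any(df$ordinal < 0)) {
    stop("ordinal must be a non-negative integer", call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    bad <- unique(df$strand[!df$strand %in% c("+", "-")])
    stop("strand outside {+,-}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$genome_id, df$locus_tag, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$locus_tag[duplicated(key)][1]
    stop("duplicate (genome_id, locus_tag): ", dup, call. = FALSE)
  }
  okey <- paste(df$genome_id, df$ordinal, sep = "\r")
  if (anyDuplicated(okey)) {
    g <- df$genome_id[duplicated(okey)][1]
    o <- df$ordinal[duplicated(okey)][1]
    stop("duplicate ordinal ", o, " within genome ", g, call. = FALSE)
  }
  df[order(df$genome_id, df$ordinal), , drop = FALSE]
}

#' Write a gene table
#'
#' @param df Gene table data.frame (see [read_gene_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a screening report
#'
#' Serialises the output of [screen_proteome()] as a tab-delimited table with
#' one row per protein: id, molecular weight (kDa, 2 decimals), signal
#' peptide (+/-), beta-strand content (%, 2 decimals), globularity (+/-),
#' porin C-terminus (+/-), size-in-window (+/-), number of criteria met, and
#' the candidate flag (+/-) — mirroring the column layout of a porin
#' candidate characteristics table.
#'
#' @param results Data.frame from [screen_proteome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  pm <- function(flag) ifelse(flag, "+", "-")
  out <- data.frame(
    id = results$id,
    mw_kda = sprintf("%.2f", results$mw_kda),
    signal = pm(results$signal_ok),
    beta_pct = sprintf("%.2f", 100 * results$frac_E),
    globular = pm(results$globular_ok),
    cterm = pm(results$cterm_ok),
    size = pm(results$size_ok),
    n_criteria = results$n_true,
    candidate = pm(results$candidate),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a screening report written by [write_report()]
#'
#' @param path Path to a report file.
#' @return Data.frame with the report columns; `+`/`-` flags become logicals,
#'   numeric columns are parsed back to numbers.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  data.frame(
    id = df$id,
    mw_kda = as.numeric(df$mw_kda),
    signal_ok = df$signal == "+",
    beta_pct = as.numeric(df$beta_pct),
    globular_ok = df$globular == "+",
    cterm_ok = df$cterm == "+",
    size_ok = df$size == "+",
    n_true = as.integer(df$n_criteria),
    candidate = df$candidate == "+",
    stringsAsFactors = FALSE
  )
}
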