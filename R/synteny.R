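# Conserved gene-order (synteny) detection for the secG-tyrS-ompA-ompB block,
# analog flagging, and a small global aligner + single-linkage clustering for
# family grouping at desk scale.

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`).
#'
#' @param a,b Protein sequences (character scalars or length-1
#'   `AAStringSet`s).
#' @param gap_open Gap opening penalty (default 11).
#' @param gap_extend Gap extension penalty per gapped position (default 1).
#' @return A list with `score` (substitution-matrix units), `aligned_a`,
#'   `aligned_b` (gapped strings of equal length) and `identity` (fraction
#'   of aligned columns with identical residues).
#' @examples
#' global_align("MKV", "MKV")$score  # 5 + 5 + 4 = 14
#' @export
global_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  a <- as.character(a)[1]
  b <- as.character(b)[1]
  if (!nzchar(a) || !nzchar(b)) {
    stop("global_align requires two non-empty sequences", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  list(score = Biostrings::score(aln),
       aligned_a = ga, aligned_b = gb,
       identity = mean(ca == cb & ca != "-"))
}

#' Group proteins into families by alignment identity
#'
#' Single-linkage clustering on pairwise global-alignment identity: two
#' proteins are linked when their identity is at least the threshold, and
#' families are the connected components. Each family is labelled by its
#' lexicographically smallest member id, so the labelling is deterministic
#' and independent of input order.
#'
#' @param records An `AAStringSet` or named character vector of sequences.
#' @param identity_threshold Linkage threshold on alignment identity
#'   (default 0.30).
#' @return Named character vector mapping record id to family label.
#' @export
cluster_families <- function(records, identity_threshold = 0.30) {
  seqs <- protein_seqs(records)
  n <- length(seqs)
  if (n == 0L) stop("at least one record is required", call. = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("record ids must be unique", call. = FALSE)
  # union-find over record indices
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (global_align(seqs[[i]], seqs[[j]])$identity >= identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(seq_len(n), function(i) {
    min(ids[roots == roots[i]])
  }, character(1))
  stats::setNames(labels, ids)
}

# Match `pattern` starting at row i of a genome's ordered loci, allowing up
# to max_gap non-matching loci between consecutive pattern slots. Returns the
# matched row indices or NULL.
.match_pattern_at <- function(fams, i, pattern, max_gap) {
  idx <- i
  if (fams[i] != pattern[1]) return(NULL)
  pos <- i
  for (p in pattern[-1]) {
    nxt <- NA_integer_
    for (step in 1:(1L + max_gap)) {
      j <- pos + step
      if (j > length(fams)) break
      if (fams[j] == p) {
        nxt <- j
        break
      }
    }
    if (is.na(nxt)) return(NULL)
    pos <- nxt
    idx <- c(idx, nxt)
  }
  idx
}

#' Find syntenic gene-order blocks
#'
#' Scans each genome for runs of consecutive loci whose family labels match
#' a pattern in order (default `secG, tyrS, ompA, ompB`). A run on the minus
#' strand matching the exact reverse of the pattern (with every locus on
#' `-`) is also reported. A run matching all but the last pattern slot,
#' where the gene occupying that slot belongs to no pattern family, is
#' reported with `analog_slot` set to that gene — the signature of a
#' non-homologous analog occupying the porin slot.
#'
#' @param gene_table Data.frame of gene loci (see [read_gene_table()]);
#'   family labels must be present (from curation or [cluster_families()]).
#' @param pattern Character vector of family labels, in gene order.
#' @param max_gap Number of intervening non-pattern genes tolerated between
#'   consecutive slots (default 0: strictly consecutive).
#' @return A list of blocks; each block is a list with `genome_id`, `loci`
#'   (the matched rows of `gene_table`, in genome order), `same_strand`,
#'   `orientation` (`"forward"`/`"reverse"`) and `analog_slot` (locus tag or
#'   `NA`).
#' @export
find_syntenic_blocks <- function(gene_table,
                                 pattern = c("secG", "tyrS", "ompA", "ompB"),
                                 max_gap = 0L) {
  if (length(pattern) < 2L || any(!nzchar(pattern)) || anyNA(pattern)) {
    stop("pattern must be >= 2 non-empty family labels", call. = FALSE)
  }
  if (anyDuplicated(pattern)) {
    stop("pattern families must be distinct", call. = FALSE)
  }
  gene_table <- validate_gene_table(gene_table)
  blocks <- list()
  k <- length(pattern)
  add_block <- function(rows, orientation, analog_slot) {
    blocks[[length(blocks) + 1L]] <<- list(
      genome_id = rows$genome_id[1],
      loci = rows,
      same_strand = length(unique(rows$strand)) == 1L,
      orientation = orientation,
      analog_slot = analog_slot
    )
  }
  for (g in unique(gene_table$genome_id)) {
    gt <- gene_table[gene_table$genome_id == g, , drop = FALSE]
    fams <- gt$family
    n <- nrow(gt)
    for (i in seq_len(n)) {
      # forward: full pattern
      idx <- .match_pattern_at(fams, i, pattern, max_gap)
      if (!is.null(idx)) {
        add_block(gt[idx, , drop = FALSE], "forward", NA_character_)
        next
      }
      # forward: all but the last slot, analog in the last position
      idx <- .match_pattern_at(fams, i, pattern[-k], max_gap)
      if (!is.null(idx)) {
        j <- idx[length(idx)] + 1L
        if (j <= n && !fams[j] %in% pattern) {
          add_block(gt[c(idx, j), , drop = FALSE], "forward", gt$locus_tag[j])
          next
        }
      }
      # reverse: full reversed pattern, uniformly minus strand
      idx <- .match_pattern_at(fams, i, rev(pattern), max_gap)
      if (!is.null(idx) && all(gt$strand[idx] == "-")) {
        add_block(gt[idx, , drop = FALSE], "reverse", NA_character_)
        next
      }
      # reverse analog: the porin slot comes first in genome order
      if (!fams[i] %in% pattern && i < n) {
        idx <- .match_pattern_at(fams, i + 1L, rev(pattern[-k]), max_gap)
        if (!is.null(idx) && all(gt$strand[c(i, idx)] == "-") &&
            idx[1] == i + 1L) {
          add_block(gt[c(i, idx), , drop = FALSE], "reverse",
                    gt$locus_tag[i])
        }
      }
    }
  }
  blocks
}

#' Flag putative analog porins in syntenic blocks
#'
#' For every block whose porin slot is occupied by a gene from outside the
#' pattern families, looks up that protein's screening result: if it carries
#' the C-terminal anchoring signature and meets at least three of the five
#' porin criteria, the verdict is `"putative analog porin"`; otherwise
#' `"unresolved"`.
#'
#' @param blocks Output of [find_syntenic_blocks()].
#' @param screen Screening results from [screen_proteome()]; protein ids
#'   must match locus tags.
#' @return Data.frame with `genome_id`, `locus_tag`, `verdict` (one row per
#'   analog slot; empty if there are none).
#' @export
flag_analogs <- function(blocks, screen) {
  out <- data.frame(genome_id = character(0), locus_tag = character(0),
                    verdict = character(0), stringsAsFactors = FALSE)
  for (b in blocks) {
    if (is.na(b$analog_slot)) next
    row <- screen[screen$id == b$analog_slot, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop("no screening result for analog slot ", b$analog_slot,
           call. = FALSE)
    }
    verdict <- if (isTRUE(row$cterm_ok[1]) && row$n_true[1] >= 3L) {
      "putative analog porin"
    } else {
      "unresolved"
    }
    out <- rbind(out, data.frame(genome_id = b$genome_id,
                                 locus_tag = b$analog_slot,
                                 verdict = verdict,
                                 stringsAsFactors = FALSE))
  }
  out
}
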