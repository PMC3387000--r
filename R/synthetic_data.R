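# Seeded generators of proteomes and gene maps with planted ground truth.
# Every operation is a pure function of its arguments: the RNG state is
# saved, seeded locally, and restored.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Per-residue sampling weights for the decoy classes, expressed as
# multiplicative factors over the Swiss-Prot background so the statistical
# structure is inspectable.
.CLASS_FACTORS <- list(
  globular   = c(I = 2.2, L = 2.2, V = 2.2, F = 2.2,
                 A = 1.5, W = 1.5, Y = 1.5, M = 1.5, C = 1.5,
                 P = 0.5, G = 0.5, S = 0.5, N = 0.5, D = 0.5,
                 Q = 0.5, E = 0.5, K = 0.5, R = 0.5),
  disordered = c(E = 3.0, S = 3.0, P = 3.0, G = 3.0, K = 3.0,
                 A = 0.3, C = 0.3, F = 0.3, I = 0.3, L = 0.3,
                 M = 0.3, V = 0.3, W = 0.3, Y = 0.3),
  ompA_like  = c(E = 2.5, A = 2.5, L = 2.5, K = 2.5,
                 P = 0.3, G = 0.5, C = 0.3, W = 0.5)
)

#' Residue sampling weights for a synthetic decoy class
#'
#' The decoy generator draws residues from the Swiss-Prot background
#' composition reweighted by class-specific factors; this returns the
#' normalised sampling distribution actually used. (Porin bodies are not
#' drawn i.i.d.; see [porin_body_pools()].)
#'
#' @param class One of `"globular"`, `"disordered"`, `"ompA_like"`,
#'   `"random"`.
#' @return Named probability vector over [AA_ALPHABET].
#' @export
class_weights <- function(class = c("globular", "disordered",
                                    "ompA_like", "random")) {
  class <- match.arg(class)
  if (class == "random") {
    return(stats::setNames(rep(1 / 20, 20), AA_ALPHABET))
  }
  f <- stats::setNames(rep(1, 20), AA_ALPHABET)
  fac <- .CLASS_FACTORS[[class]]
  f[names(fac)] <- fac
  w <- SPROT_BACKGROUND * f
  w / sum(w)
}

.draw <- function(n, weights) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = weights), collapse = "")
}

# A signal peptide conforming to the detect_signal_peptide() rules:
# n-region M + 2x(K/R) + 1 neutral, h-region of 9-12 residues from
# {L,A,V,I,F} ending in {L,A,V,I}, a polar break, then A-x-A so that the
# first (-3,-1)-conforming site is the planted cleavage site.
.make_signal <- function() {
  n_region <- c("M", sample(c("K", "R"), 2, replace = TRUE),
                sample(c("S", "T", "Q"), 1))
  hlen <- sample(9:12, 1)
  h <- sample(c("L", "A", "V", "I", "F"), hlen, replace = TRUE,
              prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
  h[hlen] <- sample(c("L", "A", "V", "I"), 1)
  brk <- sample(c("N", "Q", "H"), 1)
  sig <- c(n_region, h, brk, "A")
  list(residues = sig, cleavage_after = length(sig))
}

#' Residue pools of the synthetic porin body
#'
#' The porin body is not drawn i.i.d.: it emulates the architecture of a
#' beta-barrel, as a series of amphipathic strands (even length 10-12,
#' alternating membrane-facing hydrophobic and lumen-facing polar residues)
#' joined by short polar turns. This returns the three sampling pools with
#' their weights, so the generator's statistical structure is inspectable.
#' The resulting composition carries the porin bias: Ala, Gly, Asn, Asp and
#' Leu above a generic background; Arg, Cys, Glu, His, Ile, Met, Pro and Trp
#' below it.
#'
#' @param variant `"standard"` for the main porin family; `"analog"` for an
#'   unrelated porin family with the same architecture but shifted residue
#'   usage, so that analog sequences share only background-level alignment
#'   identity with the standard family.
#' @return A named list of three named weight vectors: `hydrophobic`
#'   (strand membrane-facing positions), `polar` (strand lumen-facing
#'   positions) and `turn`.
#' @export
porin_body_pools <- function(variant = c("standard", "analog")) {
  variant <- match.arg(variant)
  if (variant == "analog") {
    return(list(
      hydrophobic = c(I = 0.30, F = 0.25, Y = 0.25, V = 0.10, L = 0.10),
      polar = c(S = 0.28, T = 0.18, Q = 0.12, N = 0.12, G = 0.12, D = 0.10,
                K = 0.08),
      turn = c(S = 0.30, G = 0.25, D = 0.20, N = 0.15, A = 0.10)
    ))
  }
  list(
    hydrophobic = c(V = 0.34, L = 0.34, F = 0.10, Y = 0.10, I = 0.07,
                    A = 0.05),
    polar = c(T = 0.26, S = 0.20, A = 0.14, N = 0.13, G = 0.10, D = 0.08,
              K = 0.06, Q = 0.03),
    turn = c(G = 0.25, N = 0.20, S = 0.20, A = 0.20, D = 0.15)
  )
}

# Pool of polar/charged residues used for solvent-exposed segments that must
# not look like a signal-peptide h-region (every Kyte-Doolittle value < 0).
.POLAR_POOL <- c(E = 0.18, K = 0.18, D = 0.14, N = 0.12, S = 0.12,
                 T = 0.10, G = 0.10, Q = 0.06)

.draw_pool <- function(pool, k) {
  sample(names(pool), k, replace = TRUE, prob = pool)
}

# Amphipathic-barrel body: strands of even length 12-14 alternating
# hydrophobic/polar positions, separated by 3-residue polar turns.
.make_porin_body <- function(len, variant = "standard") {
  pools <- porin_body_pools(variant)
  out <- character(0)
  while (length(out) < len) {
    slen <- 2L * sample(6:7, 1)
    strand <- character(slen)
    strand[seq(1L, slen, 2L)] <- .draw_pool(pools$hydrophobic, slen / 2L)
    strand[seq(2L, slen, 2L)] <- .draw_pool(pools$polar, slen / 2L)
    out <- c(out, strand, .draw_pool(pools$turn, 3L))
  }
  paste(out[1:len], collapse = "")
}

# The C-terminal anchoring decamer, built N->C: terminal F, hydrophobic
# residues at positions 3, 5, 7, 9 (counted from the C-terminus), porin-like
# residues elsewhere.
.make_decamer <- function() {
  pos <- character(10)  # indexed from the C-terminus
  pos[1] <- "F"
  pos[c(3, 5, 7, 9)] <- sample(c("V", "I", "L", "A", "F", "Y"), 4,
                               replace = TRUE)
  even <- c(2, 4, 6, 8, 10)
  pos[even] <- sample(c("A", "S", "K", "Y", "G", "E", "Q", "T"), 5,
                      replace = TRUE)
  paste(rev(pos), collapse = "")
}

#' Generate a synthetic porin
#'
#' Builds a protein with every property the screen tests for: a conforming
#' Sec signal peptide, an amphipathic-barrel body (see
#' [porin_body_pools()]) whose composition carries the porin bias and whose
#' alternating strands give a consistently high beta-strand content and a
#' globular (downhill disorder-propensity) profile, and a C-terminal
#' anchoring decamer (terminal F, hydrophobic residues at positions 3, 5,
#' 7, 9). Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param length Total sequence length (default 410, a typical porin
#'   monomer; minimum 60 to fit signal plus decamer).
#' @param id Record id (default derived from the seed).
#' @param variant Body residue-usage family (see [porin_body_pools()]).
#' @return A list with `id`, `sequence` and `truth` (label `"porin"` or
#'   `"analog_porin"`, the planted `cleavage_after` and `decamer`).
#' @export
make_porin <- function(seed, length = 410L, id = sprintf("porin_%d", seed),
                       variant = c("standard", "analog")) {
  variant <- match.arg(variant)
  if (length < 60L) {
    stop("length must be >= 60 to fit signal peptide and decamer",
         call. = FALSE)
  }
  with_local_seed(seed, {
    sig <- .make_signal()
    decamer <- .make_decamer()
    body_len <- length - base::length(sig$residues) - 10L
    body <- .make_porin_body(body_len, variant)
    seq <- paste0(paste(sig$residues, collapse = ""), body, decamer)
    label <- if (variant == "analog") "analog_porin" else "porin"
    list(id = id, sequence = seq,
         truth = list(label = label, cleavage_after = sig$cleavage_after,
                      decamer = decamer))
  })
}

#' Generate a synthetic decoy protein
#'
#' Decoy classes emulate the non-porin proteome; each class violates several
#' screening criteria by construction:
#' \itemize{
#'   \item `globular`: hydrophobic-core composition over 160-300 residues —
#'     a typical cytoplasmic single-domain protein. Being cytoplasmic it has
#'     no export signal (the N-terminal 35 residues are solvent-exposed
#'     polar/charged residues) and no anchoring decamer (the terminal
#'     residue is never F).
#'   \item `disordered`: E/S/P/G/K-rich, 150-350 residues.
#'   \item `random`: uniform composition over the 20 residues, length
#'     60-800 (a broad null spanning the bacterial length range); nothing is
#'     forced, so rare chance passes are expected.
#'   \item `ompA_like`: long, helix-favouring E/A/L/K body mimicking toga
#'     anchor proteins: a polar SLH-like N-terminal domain (no
#'     signal-peptide-like stretch), a hydrophobic C-terminal tail but no
#'     terminal phenylalanine.
#' }
#' Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param kind One of `"globular"`, `"disordered"`, `"random"`,
#'   `"ompA_like"`.
#' @param id Record id (default derived from kind and seed).
#' @return A list with `id`, `sequence` and `truth` (label
#'   `"decoy_<kind>"` or `"ompA_like"`).
#' @export
make_decoy <- function(seed, kind = c("globular", "disordered", "random",
                                      "ompA_like"),
                       id = sprintf("%s_%d", kind[1], seed)) {
  kind <- match.arg(kind)
  with_local_seed(seed, {
    seq <- switch(
      kind,
      globular = {
        len <- sample(160:300, 1)
        nterm <- .draw_pool(.POLAR_POOL, 35L)
        core <- .draw(len - 36L, class_weights("globular"))
        cterm <- sample(c("L", "V", "I", "A", "Y", "W", "M"), 1)
        paste0(paste(nterm, collapse = ""), core, cterm)
      },
      disordered = .draw(sample(150:350, 1), class_weights("disordered")),
      random = .draw(sample(60:800, 1), class_weights("random")),
      ompA_like = {
        len <- sample(380:480, 1)
        slh <- .draw_pool(.POLAR_POOL, 45L)
        body <- .draw(len - 60L, class_weights("ompA_like"))
        tail <- sample(c("A", "L", "V", "I", "F"), 15, replace = TRUE)
        tail[15] <- sample(c("L", "A", "V"), 1)  # never a terminal F
        paste0(paste(slh, collapse = ""), body, paste(tail, collapse = ""))
      }
    )
    label <- if (kind == "ompA_like") "ompA_like" else paste0("decoy_", kind)
    list(id = id, sequence = seq,
         truth = list(label = label, cleavage_after = NA_integer_,
                      decamer = NA_character_))
  })
}

#' Generate a synthetic proteome with planted porins
#'
#' Emits `k_porins` planted porins and `n - k_porins` decoys (cycling over
#' the four decoy classes) in a seed-stable randomised order, together with
#' the ground-truth table. Fully determined by the seed.
#'
#' @param n Proteome size.
#' @param k_porins Number of planted porins (0 <= k <= n).
#' @param seed Integer seed.
#' @return A list with `proteins` (named character vector of sequences,
#'   ids `SYN_0001` ...) and `truth` (data.frame: `id`, `label`,
#'   `cleavage_after`, `decamer`).
#' @export
make_proteome <- function(n, k_porins, seed) {
  if (k_porins > n || k_porins < 0) {
    stop("k_porins must satisfy 0 <= k_porins <= n", call. = FALSE)
  }
  with_local_seed(seed, {
    sub <- sample.int(.Machine$integer.max - 1L, n)
    kinds <- rep(c("globular", "disordered", "random", "ompA_like"),
                 length.out = max(n - k_porins, 0L))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      recs[[i]] <- if (i <= k_porins) {
        make_porin(sub[i])
      } else {
        make_decoy(sub[i], kinds[i - k_porins])
      }
    }
    ord <- sample.int(n)
    recs <- recs[ord]
    ids <- sprintf("SYN_%04d", seq_len(n))
    proteins <- stats::setNames(
      vapply(recs, `[[`, character(1), "sequence"), ids)
    truth <- data.frame(
      id = ids,
      label = vapply(recs, function(r) r$truth$label, character(1)),
      cleavage_after = vapply(recs, function(r)
        as.integer(r$truth$cleavage_after), integer(1)),
      decamer = vapply(recs, function(r) r$truth$decamer, character(1)),
      stringsAsFactors = FALSE
    )
    list(proteins = proteins, truth = truth)
  })
}

#' Generate a synthetic genome map with a syntenic porin block
#'
#' Builds a ~30-gene genome containing one secG-tyrS-ompA-ompB block
#' (uniform `+` strand) surrounded by unannotated filler genes, with one
#' protein per locus: a planted porin in the ompB slot, an OmpA-like anchor
#' protein in the ompA slot, and decoys elsewhere. With `with_analog = TRUE`
#' the ompB slot instead carries an independently generated analog porin:
#' its family label is empty (no detectable homology to the porin family)
#' but it passes the C-terminal anchoring rule by construction.
#'
#' @param seed Integer seed.
#' @param with_analog Replace the ompB slot by a non-homologous analog porin.
#' @param n_genes Number of genes in the map (default 30).
#' @return A list with `genes` (a gene-table data.frame), `proteins`
#'   (named character vector, ids = locus tags) and `truth` (data.frame of
#'   planted labels).
#' @export
make_genome_map <- function(seed, with_analog = FALSE, n_genes = 30L) {
  stopifnot(n_genes >= 10L)
  with_local_seed(seed, {
    genome_id <- sprintf("syngenome_%d", seed)
    sub <- sample.int(.Machine$integer.max - 1L, n_genes + 1L)
    block_start <- sample(3:(n_genes - 6L), 1)  # ordinal of the secG gene
    ordinals <- 0:(n_genes - 1L)
    tags <- sprintf("SG%d_%04d", seed %% 1000L, ordinals)
    family <- rep("", n_genes)
    bi <- block_start + 1L  # row index of the secG gene (ordinals 0-based)
    family[bi:(bi + 2L)] <- c("secG", "tyrS", "ompA")
    family[bi + 3L] <- if (with_analog) "" else "ompB"
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    strand[bi:(bi + 3L)] <- "+"
    genes <- data.frame(genome_id = genome_id, locus_tag = tags,
                        ordinal = ordinals, strand = strand,
                        family = family, stringsAsFactors = FALSE)
    labels <- character(n_genes)
    proteins <- character(n_genes)
    kinds <- c("globular", "random", "disordered")
    for (i in seq_len(n_genes)) {
      if (i == bi + 3L) {
        rec <- make_porin(sub[i], id = tags[i],
                          variant = if (with_analog) "analog" else "standard")
        labels[i] <- rec$truth$label
      } else if (i == bi + 2L) {
        rec <- make_decoy(sub[i], "ompA_like", id = tags[i])
        labels[i] <- "ompA_like"
      } else {
        kind <- kinds[(i %% length(kinds)) + 1L]
        rec <- make_decoy(sub[i], kind, id = tags[i])
        labels[i] <- rec$truth$label
      }
      proteins[i] <- rec$sequence
    }
    names(proteins) <- tags
    truth <- data.frame(id = tags, label = labels, stringsAsFactors = FALSE)
    list(genes = genes, proteins = proteins, truth = truth)
  })
}
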