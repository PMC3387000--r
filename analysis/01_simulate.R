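#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emits a 500-protein proteome with 20 planted porins (seed 1), the five
# synthetic reference porins the screen compares beta content against, and
# two ~30-gene genome maps: one with an orthologous porin in the
# secG-tyrS-ompA-ompB block and one where that slot holds a non-homologous
# analog porin. Everything is written as FASTA / tab-delimited text under
# results/simulated/.

suppressMessages(library(togascreen))

outdir <- file.path("results", "simulated")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

seed <- 1L
n <- 500L
k <- 20L

proteome <- make_proteome(n, k, seed = seed)
write_fasta(proteome$proteins, file.path(outdir, "proteome.fasta"))
write.table(proteome$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

refs <- vapply(9001:9005, function(s) make_porin(s)$sequence, character(1))
names(refs) <- paste0("ref_", 9001:9005)
write_fasta(refs, file.path(outdir, "references.fasta"))

for (variant in c("ortholog", "analog")) {
  gm <- make_genome_map(seed = seed, with_analog = variant == "analog")
  write_gene_table(gm$genes, file.path(outdir, paste0("genes_", variant, ".tsv")))
  write_fasta(gm$proteins, file.path(outdir, paste0("proteins_", variant, ".fasta")))
  write.table(gm$truth, file.path(outdir, paste0("truth_", variant, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

lbl <- table(proteome$truth$label)
cat("Simulated proteome:", n, "proteins,", k, "planted porins (seed", seed, ")\n")
cat("  decoy mix:", paste(names(lbl), lbl, sep = "=", collapse = ", "), "\n")
cat("  reference porins:", length(refs), "\n")
cat("  genome maps: one ortholog block, one analog block (~30 genes each)\n")
cat("Written under", outdir, "\n")
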