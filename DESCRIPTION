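Package: togascreen
Title: Sequence-Based Screening for Outer-Membrane Porin Candidates in
    Thermotogales Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens bacterial proteomes for candidate toga porins using five
    sequence-derived criteria: molecular size, a rule-based Sec signal-peptide
    call, Chou-Fasman beta-strand content compared against reference porins, a
    disorder-propensity globularity assessment, and the C-terminal beta-barrel
    anchoring signature (terminal phenylalanine with hydrophobic residues at
    alternating positions of the last decamer). Also scores porin-like amino
    acid composition bias, detects conserved secG-tyrS-ompA-ompB gene-order
    (synteny) blocks across genomes, flags putative non-homologous analog
    porins occupying the ompB slot, and ships a seeded synthetic proteome and
    gene-map generator with planted ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
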