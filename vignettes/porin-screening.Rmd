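---
title: "Methods: sequence-derived porin screening and synteny analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-derived porin screening and synteny analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(togascreen)
```

## The problem

β-barrel porins diverge in primary sequence far faster than in
architecture, so alignment-based search fails across deep lineages.
What survives divergence is a bundle of sequence-intrinsic fingerprints:
a monomer mass near 42 kDa, an N-terminal Sec export signal, a
β-strand-rich fold, compact (globular) domain structure, and a
C-terminal membrane-insertion signature — a terminal phenylalanine with
hydrophobic residues at alternating positions of the last decamer.
`togascreen` encodes each fingerprint as one boolean criterion and calls
a protein a porin *candidate* at ≥ 3 of 5 and a *strong* candidate at
5 of 5. Because the historical screens behind this logic used web tools
that cannot be re-run reproducibly, every predictor here is an internal,
fully specified heuristic: results are deterministic functions of the
sequence and the documented constants.

## Physicochemical layer

**Molecular weight.** The sum of Expasy average residue masses plus one
water (`AA_AVG_MASS`, `WATER_MASS`). Average, not monoisotopic, because
the candidate tables this screen mirrors were produced by
ProtParam-style calculators. Reported in kDa to 2 decimals.

**Composition.** Counts and fractions over the 20 canonical residues.
`X` may be admitted at parse time (`allow_x`); it is excluded from every
denominator and treated as non-hydrophobic.

**Hydropathy.** Kyte–Doolittle per-residue values with sliding-window
means; a window of 9 is the conventional default for soluble-region
scans, and the signal-peptide rule uses windows of 7 internally.

**Hydrophobic sets.** Two sets back the C-terminal signature:
`kd_positive` = {A,C,F,I,L,M,V} (positive Kyte–Doolittle values) and
`extended` = `kd_positive` ∪ {W,Y}. The extended set is the default: the
published decamer tables of reference porins mark membrane-facing W and
Y as hydrophobic, and only the extended set reproduces those markings.
The printed tables are themselves not fully consistent about Y, which is
exactly why the set is exposed as configuration rather than hard-coded.

## Structure-prediction layer

**β-strand content (Chou–Fasman).** Classic single-sequence propensity
prediction: helices nucleate where 4 of 6 consecutive residues have
helix propensity > 100 and extend while the mean of the 4-residue window
crossing the boundary stays ≥ 100; strands nucleate at 3 of 5 residues
with strand propensity > 100, same extension rule. Residues claimed by
both states go, segment-wise, to the state with the larger summed
propensity; ties favour strand (the screen's subject is β-rich
proteins; the tie is essentially theoretical since summed propensities
over a segment rarely coincide). Chou–Fasman was chosen over trained
predictors because it is fully specified by published constant tables —
no training data, no model files, no drift. Its absolute numbers are
crude; the screen therefore **never** compares a predicted fraction to a
percentage printed by some other tool. Criterion 3 only asks whether the
candidate's strand fraction falls inside the range spanned by reference
porins *predicted by this same function*, widened by ± 0.05. Sequences
shorter than 6 residues cannot nucleate and are returned all-coil with a
`too_short` flag instead of an error, so proteome-wide screens tolerate
degenerate records.

**Sec signal peptide.** Three rules on the first 45 residues: (n) K or R
within residues 1–7; (h) a ≥ 7-residue window within residues 4–25 with
mean Kyte–Doolittle ≥ 1.6; (c) the first cleavage site 10–45 residues in
satisfying the (−3,−1) small-residue rule (−1 ∈ {A,G,S,C,T}, −3 ∈
{A,G,S,C,T,V,I,L}) at least 2 residues after the h-region ends. The
h-region's right edge needs a decision: extending by *window means*
would let a hydrophobic core swallow the downstream c-region (mean
windows stay high across one or two polar residues), which contradicts
the behaviour the rule set is meant to capture. The implementation fixes
the start at the first qualifying 7-window and then extends
residue-by-residue while the individual Kyte–Doolittle value stays
≥ 1.6. Thresholds (window 7, KD ≥ 1.6, site range 10–45) are engineering
defaults exposed in `screen_config()`, not biological constants.
Sequences under 30 residues are never called (`too_short`).

**Globularity.** Per-residue Russell–Linding disorder propensities are
summed along the chain; the curve is smoothed with a centred moving
average (window 15, shrinking at the edges); maximal non-increasing
stretches of the smoothed curve spanning ≥ 40 residues are globular
domains; the protein is globular at ≥ 50 % domain coverage. One
centring choice matters: the running sum could be taken over raw
propensities or over propensities minus the table mean. The propensity
scale is already a difference measure (random-coil versus
regular-structure preference), and subtracting the table mean makes any
composition enriched in G/N/D — i.e. every real porin — drift uphill
and read as non-globular, which is the opposite of how running-sum
globularity tools classify real porins. The `center` parameter therefore
defaults to 0 (raw sum); a compositionally average protein drifts mildly
downhill, disorder-biased sequences climb. The consequence that
uniform-random sequences are often called globular is accepted and
accounted for in the benchmark design below.

## The screen

`evaluate_candidate()` assembles the five criteria; any component
failure on a degenerate sequence yields a `FALSE` criterion, never an
abort. `screen_proteome()` ranks by (number of criteria met, descending;
distance from 42 kDa, ascending; record id) — a total, deterministic
order. The size window 35–50 kDa is centred on the ~42 kDa porin monomer
and deliberately generous: it keeps heavier homologs near 49 kDa inside
while excluding clearly small proteins, matching how the historical
candidate set was drawn. The composition-bias score is reported
alongside but is *not* one of the five criteria: it counts how many of
the 13 diagnostic residues (8 expected low, 5 expected high) behave as
expected against the Swiss-Prot background, with `porin_like` at
≥ 8/13. The C-terminus rule defaults to *relaxed* (terminal F plus ≥ 3
of positions 3,5,7,9 hydrophobic): the published homolog/analog tables
mark decamers with one non-hydrophobic odd position as passing, so only
the relaxed rule reproduces them; *strict* is available in
configuration.

## Synteny and analogs

Gene tables carry ordinal positions, not coordinates: the conserved
`secG–tyrS–ompA–ompB` argument depends only on gene order and
orientation. `find_syntenic_blocks()` matches the family pattern over
strictly consecutive ordinals (a `max_gap` option admits intervening
genes); a run on the minus strand must match the exact reversed pattern
with uniform `-` strand — mixed-strand runs are not blocks. A run
matching all but the porin slot, where that slot's gene belongs to no
pattern family, is reported with `analog_slot` set: the signature of a
non-homologous stand-in. `flag_analogs()` renders
`"putative analog porin"` when the slot protein carries the relaxed
C-terminal signature and ≥ 3 criteria, else `"unresolved"`.

Family grouping at desk scale uses optimal global alignment (BLOSUM62,
affine gaps 11/1, a gap of length L costing 11 + L) with single-linkage
clustering at 0.30 identity, each family labelled by its
lexicographically smallest member. Profile search against reference
databases is explicitly out of scope; gene tables may instead carry
curated family labels, so known topologies can be encoded directly as
fixtures. Identity is the fraction of aligned columns (gaps included)
with identical residues.

## The synthetic-data generator

The generator defines the study conditions for every benchmark; its
defaults are fixed and not tuned per run.

**Porins** (`make_porin`, default 410 residues): a conforming signal
peptide (M + two K/R + neutral residue; 9–12 residue L/A/V/I/F h-region
ending in a (−3)-compatible residue; polar break; planted A cleavage
site, typically 17–20 residues in), then an amphipathic-barrel body,
then an anchoring decamer (terminal F, hydrophobic 3/5/7/9). The body is
*not* an i.i.d. draw: it alternates membrane-facing hydrophobic and
lumen-facing polar positions in strands of 12–14 residues joined by
3-residue polar turns (`porin_body_pools()`). This mirrors real barrel
architecture and is load-bearing for two reasons: it concentrates the
β-signal (consistently high Chou–Fasman strand fractions, giving a tight
reference range), and it makes the disorder running sum reliably
downhill, so planted porins are globular under the default detector
parameters — an i.i.d. draw of the same composition is a coin flip,
because 40-residue monotone stretches are fragile against composition
noise. The resulting composition carries the porin bias (A, G, N, D, L
above background; R, C, E, H, I, M, P, W below). One conscious
resolution: Ile is both a β-former and one of the porin-depleted
residues; depletion wins, as it does in real porins, and the β-signal is
carried by V/Y/T/F instead.

**Decoys** (`make_decoy`) each violate several criteria *by
construction*: `globular` decoys (160–300 residues, hydrophobic core)
have a polar 35-residue N-terminus — they model cytoplasmic proteins,
which have no export signal — and never end in F; `disordered` decoys
are E/S/P/G/K-rich; `ompA_like` decoys model toga anchor proteins
(helix-favouring E/A/L/K body, polar SLH-like N-terminal domain,
hydrophobic C-terminal tail without terminal F); `random` decoys are
uniform over the alphabet with lengths 60–800 and nothing forced — they
supply the honest false-positive floor, and single random decoys pass
the 3-criterion line only a few percent of the time (size ∧ globular ∧
one more). `analog` porins reuse the barrel architecture with a shifted
residue-usage family, so they pass the screen while sharing only
background-level (~0.2) alignment identity with the standard family —
below the 0.30 clustering threshold.

**What the generator does not emulate:** real phylogenetic divergence
(synthetic "families" are statistical, not evolutionary), nucleotide
context, operon structure beyond gene order, chaperone-dependent
membrane insertion, and the true composition correlations of natural
proteomes. Passing benchmarks therefore demonstrates that the screen's
logic recovers the planted structure it formalises — not that it would
achieve the same sensitivity/specificity on a real proteome.

All generator operations are pure functions of their seed: the RNG state
is saved, seeded locally, and restored.

## Numerical and testing choices

* Window means use exact cumulative sums; no floating-point drift
  accumulates beyond machine epsilon, and determinism is asserted
  byte-for-byte on written artifacts.
* Report files round molecular weight and β-percentages to 2 decimals;
  re-parsing and re-writing a report reproduces it byte-identically.
* The alignment oracle (exhaustive enumeration of gapped alignments)
  is exponential per pair, so the equivalence suite sweeps all pairs up
  to length 2 over a 4-letter alphabet exhaustively and samples longer
  pairs (lengths 3–6) under a fixed seed — enumeration over *all*
  length-≤ 6 pairs would be ~10^7 pairs and is neither necessary nor
  affordable.
* The C-terminus classifier is checked against a literal re-statement of
  the rule over an 8 000-decamer grid (every terminal residue ×
  hydrophobic/non-hydrophobic odd-position combination × randomised even
  positions).
* Benchmark problem sizes — 500 proteins with 20 planted porins, 5
  references, ~30-gene genome maps — are the package's chosen study
  conditions: large enough that sensitivity and false-positive counts
  are meaningful, small enough that the whole suite runs in about a
  minute.
* Degenerate inputs (empty proteomes, sub-decamer sequences, sub-window
  profiles) return empty/false results with explicit reasons rather
  than erroring mid-screen.

## Known limitations

The heuristics are deliberately simple: Chou–Fasman mislabels many real
structures; the signal rule has no notion of lipoprotein signals or
twin-arginine export; the globularity detector sees composition, not
packing; uniform-random sequences of the right length can clear three
criteria. The screen's value is in combining weak signals and in being
exactly reproducible, not in any single predictor's accuracy. Verdicts
are screening calls, not annotations: on real data, a candidate list is
where laboratory work starts, not where it ends.
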