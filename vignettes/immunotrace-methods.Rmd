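---
title: "Annotating innate-immunity gene repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating innate-immunity gene repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunotrace)
```

## The problem

Arthropod genomes encode recognisable families of innate-immunity genes —
peptidoglycan recognition proteins (PGRPs), beta-glucan recognition
proteins derived from GH16 glucanases, thioester-containing proteins
(TEPs), Toll-like receptors (TLRs), Relish-type NF-kB factors, and
Nimrod-superfamily phagocytosis receptors. Annotating these repertoires in
a newly predicted proteome is not a single BLAST search: family membership
must be supported by several independent lines of evidence, and the
biologically interesting questions (is this PGRP an active amidase? can
this TEP still form a thioester bond? is this receptor a single- or
multiple-cysteine-cluster TLR?) are decided by individual residues, short
motifs, and domain architectures, not by overall similarity.

`immunotrace` implements that procedure end to end as a reusable,
deterministic pipeline, and ships a synthetic-proteome generator with full
ground truth so that every stage is testable without downloading genomes.

## Evidence model

A candidate protein is annotated with a family when it has at least one of
three independent evidence sources, and survives two filters:

1. **Reciprocal best hit (RBH).** All-vs-all local alignment
   (Smith–Waterman, affine gaps, BLOSUM62, gap open 11 / extend 1) links
   each protein to its best hit in the reference species; a pair counts
   only when each is the other's top scorer. Raw scores are converted to
   bit scores and e-values with fixed Karlin–Altschul constants
   (`K = 0.041`, `lambda = 0.267`, the standard gapped-BLOSUM62 values);
   these serve only to apply thresholds, not as calibrated statistics.
   Hits survive only with e-value `< 1e-6`, identity `> 20%`, and bit
   score `> 80` (strict inequalities).
2. **Orthogroup co-clustering.** Orthogroups are connected components of
   the graph whose edges are reciprocal filtered hits. This is a
   deliberate, fully deterministic simplification of Markov-clustering
   orthology tools: it is oracle-checkable at desk scale, and its label
   propagation rule (a group inherits the family of a labelled reference
   query; conflicting labels flag the group ambiguous) is explicit.
3. **Profile/motif evidence.** Domain models are ungapped
   position-specific scoring matrices (PSSMs) built from reference
   alignments; diagnostic degenerate motifs (the NIM 26-mer, GCGEQ, the
   bundled RHIM consensus) are matched exactly at their fixed positions
   with `X` as a wildcard. Profile-style hidden Markov models would be
   more sensitive to remote homology; the PSSM design was chosen because
   it is fully specifiable and testable against a brute-force oracle, and
   the tabular interfaces accept externally produced domain tables for
   users who prefer HMM searches.

The two filters are (a) the **architecture rule** — every required domain
present at its minimum count, no forbidden domain, required motifs found,
localization as expected — and (b) the **reciprocal-hit veto**: when a
protein's best reciprocal reference hit exists but is not a member of the
assigned family, the candidate is rejected. We read the evidence-combining
procedure conjunctively (architecture **and** reciprocal agreement must
hold); the alternative disjunctive reading would accept candidates whose
reciprocal hit contradicts the family call, which defeats the veto's
purpose.

When evidence points at several families the record is assigned to the
family with the most independent sources; exact ties are rejected with a
reason rather than resolved arbitrarily.

## Functional classification

* **PGRP catalytic state.** Amidase activity requires a zinc-binding
  triad (one cysteine, two histidines). Members are aligned with an
  annotated reference; a member is `catalytic` iff all three mapped
  positions hold the expected residues. A gap at an anchored position is
  reported as `-` and is non-catalytic. The anchor positions are
  configuration shipped with the bundled annotated reference — they are
  properties of the chosen reference sequence, not universal constants.
* **Glucanase activity.** Two active-site glutamates, numbered 188 and
  193 on the annotated reference's own coordinates, decide activity;
  proteins lacking either are flagged (the "asterisk" class).
* **TEP class.** Presence of the canonical thioester motif `GCGEQ`
  separates TEPs from MCR-like proteins. When the motif is absent, the
  critical cysteine is sought within ±10 residues of the degenerate
  (`GXGEQ`) site — a pragmatic window, since "near the motif context" is
  otherwise undefined without a curated alignment.
* **TLR structure.** The ectodomain's cysteine clusters (windows of ≤ 12
  residues holding ≥ 2 cysteines, greedy left-to-right) classify
  receptors: exactly one juxtamembrane cluster → `scc`; exactly two
  clusters → `mcc`; anything else (including more than two) →
  `atypical`, with the count reported. Receptors with an ectodomain
  shorter than 150 residues are flagged truncated. TLR domain order
  follows the canonical receptor layout: LRR ectodomain at the
  N-terminus, transmembrane helix, cytosolic C-terminal TIR domain.
* **Relish architecture.** `has_ankyrin_region` requires at least two
  ankyrin-repeat hits C-terminal of the Rel homology domain; ankyrins
  N-terminal of the RHD do not count.

## Structural feature heuristics

The feature predictors are deliberately simple, documented heuristics
standing in for dedicated web-service predictors; they are calibrated for
the strongly hydrophobic, cleanly separated features the synthetic data
plants, and results on real proteomes should be interpreted with that
caveat.

* **Transmembrane helices:** Kyte–Doolittle window of 19, mean > 1.6,
  runs trimmed to ≥ 15 residues.
* **Signal peptides:** a hydrophobic core of ≥ 8 residues within the
  first 30, rejected when the stretch is the start of a TM segment
  extending past residue 35 (signal anchor).
* **Localization:** TM segment starting after residue 35 →
  `transmembrane`; else signal peptide → `secreted`; else
  `intracellular`.
* **LRRs:** the degenerate core consensus `LxxLxLxxNxL`
  (L ∈ {L,I,V,F}, N ∈ {N,C,T,S}), matches merged when within 5 residues.
* **Cysteine clusters:** window 12, minimum 2 cysteines, juxtamembrane
  when within 30 residues of the first TM start. These constants are
  package definitions — "cysteine cluster" has no formal definition in
  the literature this models.

## PSSM thresholds

A PSSM's detection threshold is calibrated at build time: the minimum
self-score of the training rows minus a per-column margin (default 2 log2
units per model column). The arithmetic behind the default: substituting
one well-conserved column costs roughly 7–8 log2 units, so a margin of
2/column tolerates about 25% column divergence beyond the training rows,
while an unrelated sequence scores about −3 log2 units per column in
expectation and stays far below any plausible threshold. The default
background is the training-set composition smoothed 1:1 with the uniform
distribution — a small training sample must not assign near-zero
background probability to unseen letters, which would make them score
positive everywhere. Overlapping hits are reduced greedily by descending
score; scores are compared at 1e-6 resolution so ties cannot depend on
floating-point summation order.

## Alignment machinery

Pairwise local alignment and profile–profile merging run in compiled code
with a documented deterministic traceback (diagonal > up > left; among
equal end cells the smallest row, then column, wins). A gap of length *k*
costs `open + k · extend`. The progressive aligner builds its guide tree
by neighbor joining on `1 − identity` distances from pairwise local
alignments — simple and adequate for the within-family alignments it
serves. The all-vs-all stage seeds candidate pairs by shared unique
tetramers (at least `max(4, 0.02 · min(length))` in common) before dynamic
programming, in the spirit of word-seeded search tools; unrelated pairs
almost never pass the seed, and pairs that could survive the bit-score
threshold share far more words than the seed requires.

## Trees

Gene trees are neighbor-joining trees on Poisson-corrected mismatch
distances, midpoint-rooted, with bootstrap support from column resampling
(support reported as integers 0–100). Maximum-likelihood inference is out
of scope by design: NJ on corrected distances is exact on additive
matrices (a testable property), and the Newick interfaces let users import
externally built ML trees. Negative NJ branch lengths are clamped to zero
with the deficit moved to a sibling branch. For families with only three
members a plain tree is built without bootstrap — a three-taxon tree has
no internal bipartition to support.

## The synthetic-proteome generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline's claims are validated.

* **Species.** Four species on a balanced tree (`refsp` plays the
  reference role); terminal branch lengths equal the configured
  divergence (default 0.05 substitutions/site, the "recoverable"
  setting; 0.4 is the stress setting), internal branches half that.
* **Families.** Six families with small ancestral copy numbers (PGRP 3,
  GH16 2, TEP 2, TLR 2, Relish 1, Nimrod 2). Each ancestral copy gets its
  own template: shared domain consensus blocks plus copy-specific random
  linkers, so paralogs are distinct while orthologs remain recognisable.
* **Copy-number evolution.** A linear birth–death process per lineage
  along each branch (default duplication 0.3, loss 0.15 per unit branch
  length — modest rates that keep families stable but exercised). Mean
  tip copy number has the closed form `n0 · e^{(b−d)t}`, which the test
  suite checks at 3 standard errors.
* **Sequence evolution.** I.i.d. substitution at probability equal to
  branch length, replacement uniform over the other 19 letters. There is
  no rate matrix and no indel process: the classifiers under test are
  residue- and motif-based, and the simple process keeps every
  expectation closed-form. Diagnostic features (anchors, motifs, TM,
  signal core, cysteine clusters, LRR consensus positions) are protected
  from substitution except when explicitly ablated — divergence is
  applied to the parts of the sequence the classifiers do not read, so
  that functional truth stays well-defined at every divergence.
* **Functional variation.** Anchor ablation (PGRP triad, GH16 glutamate
  pair) and thioester-motif ablation at probability 0.4 per tip copy;
  scc/mcc architecture and RHIM presence per ancestral copy; Relish
  ankyrin truncation at 0.3. Ectodomain linkers are cysteine-free so
  planted clusters are the only clusters, and leading linkers of
  intracellular constructs are hydrophilic so they cannot mimic a signal
  core by chance.
* **Background.** 200 unrelated random proteins per species
  (gamma-distributed lengths, mean ≈ 330, clipped to 80–1200), drawn
  from a fixed average amino-acid composition; they carry no planted
  features and exercise the false-positive controls.

What passing tests on this generator do **not** show: performance on real
proteomes with indels, splice variants, compositional bias, fragmented
gene models, or genuinely remote homology. The generator emulates the
decision structure of the annotation problem, not the full texture of
genome data.

## Validation protocol and problem sizes

The package's acceptance checks (also re-run by `scripts/acceptance.R`)
use these problem sizes, chosen to finish comfortably on a single CPU
while leaving no stage untested: 200 random pairs against a full-DP
alignment oracle; 1000 random sequences against a regex motif oracle; 100
random sequence/PSSM pairs against a sliding-window oracle; 500 random
gapped alignments for coordinate round-trips; 100 random 8-leaf additive
matrices for NJ exactness; 100 random trees for the midpoint property;
the full 4-species/6-family/200-background dataset for noise-free
end-to-end recovery (precision = recall = 1 and 100% functional
agreement are *required* there, since nothing is degraded); the same
dataset at 0.4 substitutions/site for the degraded regime (precision must
stay ≥ 0.95; recall is reported, not asserted — at that divergence the
PSSM models intentionally stop detecting their domains and the
architecture filter rejects what alignment alone would still find); 500
birth–death replicates for the copy-number expectation; and a planted
two-clade alignment for bootstrap behaviour.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in R-facing structures and
  reports (matching residue numbering such as "E188"); the compiled
  kernels translate internally.
* Stop codons (`*`) at sequence ends are stripped silently; an internal
  `*` is a loud error — truncated gene models should fail, not pass
  quietly. `X` is accepted and scores 0 in all schemes.
* Haplotype collapse merges within-species pairs at ≥ 99% global
  identity, keeping the longer sequence; the threshold replaces
  tree-based manual inspection with an explicit numeric rule.
* Orthogroups without any labelled reference member are kept, unlabelled,
  rather than discarded.
* The substitution matrix and gap penalties are the standard
  protein-search defaults; the upstream procedure this package models
  does not state them, so they are assumptions, and are exposed as
  configuration.
* The bundled RHIM consensus is a configuration default (the motif's
  published models are alignment-based); users can replace it per run.
* All randomness flows from a single seed; identical configuration and
  seed give byte-identical output bundles, which the test suite checks
  literally.

## Limitations

Ungapped PSSMs lose remote homologs that profile HMMs would find; the
heuristic TM/signal predictors are not substitutes for dedicated tools on
real data; connected-component orthogroups can chain families together
through promiscuous domains (the synthetic families are disjoint by
construction, real ones need not be); and NJ trees are input to
interpretation, not a substitute for ML inference when topology matters.
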