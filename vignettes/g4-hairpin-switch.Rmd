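---
title: "Scoring and classifying G-quadruplex/hairpin switch sequences"
author: "g4switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying G-quadruplex/hairpin switch sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4switch)
```

## The problem

A DNA sequence with four runs of three or more guanines (G-tracts) can fold
into an intramolecular G-quadruplex (G4), a four-stranded structure of
stacked G-quartets stabilized by monovalent cations, much more strongly by
K⁺ than by Na⁺. When the loops between the G-tracts also contain runs of
cytosines, the same molecule can instead fold into a Watson–Crick hairpin in
which the C-runs pair with the G-tracts. Which fold predominates then
depends on the Na⁺/K⁺ balance of the buffer: the hairpin's stability is
essentially cation-ratio-independent, while the G4's grows with [K⁺]. Such
sequences behave as ionic-condition-dependent shape-shifters, which matters
for aptamer design (extracellular fluid is Na⁺-rich) and for interpreting
putative quadruplex sequences (PQS) in genomes, roughly a tenth of which
carry at least one CCC run.

`g4switch` provides the desk-scale computational side of this picture:

1. **G4Hunter scoring** (`score_bases()`, `g4hunter_score()`,
   `window_scan()`) — the classic run-length score and a softened C-run
   penalty variant.
2. **PQS motif detection** (`find_pqs()`, `pqs_census()`) — four motif
   classes, strand-aware, with BED output.
3. **Cytosine-run analysis** (`c_profile()`) — the N statistic and discrete
   CCC-run counts.
4. **Hairpin capacity** (`max_hairpin_pairs()`, `stem_report()`) — maximal
   nested G-C pairing by dynamic programming with dot-bracket traceback.
5. **Phase classification** (`classify_switch()`, `predict_fold()`) — the
   three-regime call (G4-locked / switchable / hairpin-locked) with a
   potassium threshold.
6. **Fixtures** (`ceb_family()`, `synth_genome()`) — the CEB25 mutant
   family and planted-motif synthetic genomes.

## The model sequence family

The test-bed is the human minisatellite CEB25 G4 (here `CEBwt`), a parallel
G4 with a 9-nt central loop, and nine derivatives in which central-loop
bases are progressively replaced by cytosines or the 3' end is extended
with C-run tails:

```{r family}
score_table(ceb_family())
```

The cytosine load is summarized by the N statistic, *N* = (total C)/3, a
fractional "number of CCC motifs". It is deliberately distinct from
`ccc_runs`, the count of discrete maximal C-runs of length ≥ 3: CEBm2 has
four cytosines in one CCC run plus an isolated C, so *N* = 1.33 but
`ccc_runs` = 1. The genome census filters use `ccc_runs`; the phase
classifier uses *N* (see below).

## G4Hunter scoring and the softened C-run penalty

The classic rule scores each G in a maximal G-run of length *L* as
+min(*L*, 4) and each C in a maximal C-run as −min(*L*, 4); A, T and N
score 0; the G4Hunter score is the mean over all bases. The score is
antisymmetric under reverse complement and bounded by ±4.

Because C-runs are penalized by the full −3 per base, PQS that carry CCC
runs score low even when experiment shows they can still form a G4 at high
[K⁺] (CEBm4 scores 0.69, below common hit thresholds, yet folds into a G4
above 40 mM K⁺). The soft scheme therefore replaces the per-C penalty in
any C-run of length ≥ 3 with a fixed magnitude (2 or 1.5 being the
recalibrations of interest), leaving runs of one or two cytosines at −1/−2:

```{r soft}
g4hunter_score(ceb_family()[[7]], scoring_scheme("soft", 2))    # 24/26
g4hunter_score(ceb_family()[[7]], scoring_scheme("soft", 1.5))  # 27/26
```

Two numerical choices: presentation rounding is half-away-from-zero to two
decimals (`round_half_away()`), which is what reproduces 39/26 → 1.50 and
24/26 → 0.92; and the soft penalty applies to every C-run of length ≥ 3,
not only exact triplets — the minimal consistent extension, untestable on
this family whose C-runs are all of length 3 (a run of length ≥ 4 would
otherwise score *less* harshly per base under the classic cap than a
triplet under the soft rule, which would be incoherent).

`window_scan()` scores each window as a standalone subsequence: a run
truncated by the window boundary contributes by its length *inside* the
window. Defaults (window 25 nt, step 1, |mean| ≥ 1.2) follow common
genome-scan practice; whole-sequence scoring is the default for oligos.

## PQS motif classes

`find_pqs()` implements four validated motif classes: classical (four
tracts of ≥ 3 G, loops 1–7 nt), long-loop (exactly one loop 8–15 nt),
bulged (one tract is a G-triplet split by a single 1–7 nt non-G bulge,
with ≥ 1 G on each side), and G-vacancy (one tract has only GG). Two-tetrad
G4s are out of scope (generally of low thermal stability).

The hit definition is deliberately conventional where the field's databases
do not publish an exact grammar: greedy shortest match (minimal tracts,
minimal loops) at the leftmost anchor; overlapping same-class hits merged
into the leftmost representative (`report_all = TRUE` disables merging);
and class precedence classical > long-loop > bulged > vacancy when a locus
satisfies several classes, which makes multi-class loci deterministic. A
minus-strand hit is a C-motif whose reverse complement satisfies the class;
its decomposition is reported on the motif (G-rich) strand. Coordinates are
0-based half-open internally and in BED output.

```{r pqs}
find_pqs(ceb_family()[[1]], both_strands = FALSE)[, 1:6]
```

## Hairpin capacity by maximal nested pairing

The competing-hairpin potential is quantified as the maximum number of G-C
base pairs formable in a nested (non-crossing, pseudoknot-free) pairing
with a minimum loop length — a Nussinov-style maximum-cardinality dynamic
program, O(n³) in sequence length, with A-T pairs optionally counted. It is
a pair-*counting* model: no nearest-neighbor thermodynamics, no G-T wobble,
no pseudoknots, which is the right level for asking "how many G-C pairs
could this sequence ever recruit away from its G-tracts".

```{r hairpin}
fold <- max_hairpin_pairs(ceb_family()[[8]], min_loop = 1)
fold
stem_report(fold)
```

`min_loop = 1` is used for the *capacity* statistic (CEBm5 → 9 G-C pairs,
also its composition bound min(#G, #C)); `min_loop = 3` is the sterically
realistic default for fold reports. Among co-optimal pairings the traceback
pairs the outermost compatible positions first (leftmost base with its
farthest partner), a documented deterministic tie-break. The DP is verified
against an exhaustive enumeration oracle on random sequences up to length
18 in the test suite.

## The three-regime phase classification

At low temperature the predominant species falls into one of three regimes
as a function of the Na⁺/K⁺ balance:

* **G4-locked** — G4 predominates at every balance, even with 0 mM K⁺;
* **switchable** — hairpin at low [K⁺], G4 once a sequence-dependent
  potassium threshold is reached;
* **hairpin-locked** — hairpin at every balance.

The default rule table keys the regime on the N statistic together with the
hairpin capacity: *N* ≤ 1 (and capacity < 6 G-C bp) → G4-locked; *N* ≥ 3 →
hairpin-locked; otherwise switchable. N, not the discrete CCC-run count, is
the driver: one CCC run plus one or two extra cytosines (N = 1.33, 1.67)
already shifts the equilibrium toward the hairpin at low [K⁺], while a
single clean CCC (N = 1) barely influences G4 formation. A rule keyed on
discrete runs could not separate those cases.

For switchable sequences the potassium threshold is interpolated linearly
on a calibrated ladder: N = 4/3 → 15 mM, 5/3 → 25 mM, 2 → 40 mM,
continued linearly down to (1, 0 mM) and, above N = 2, with the final
segment's slope, capped at 140 mM. The 15 mM point is low-confidence (the
melting profile at that balance is ambiguous; the G4 signature there rests
on thermal-difference spectra). All thresholds are a plain-text YAML config
away (`read_rule_table()` / `write_rule_table()`).

```{r classify}
classify_table(ceb_family(), buffers = ceb_buffers()[c("B1", "B5", "B9")])
```

Two caveats are built in. The classifier is an equilibrium call at low
temperature: the temperature axis of the phase diagram is out of its
quantitative scope. And hairpin-to-G4 conversion can be kinetically very
slow (hours to days; a pre-formed hairpin acts as a kinetic trap), so a
switchable call predicts the equilibrium species, not the species minutes
after a K⁺ jump — every switchable `switch_call` carries this caveat
string.

## The synthetic-genome generator

`synth_genome()` emulates the one property the detector tests need from a
genome: known ground truth. The background is i.i.d. at a chosen GC
fraction (default 0.4, roughly genomic) with G/C-run suppression (no
background G- or C-run of length ≥ 3), so no PQS can arise by chance;
planted motifs have A/T-only loops, an 8-nt forced A/T flank on both sides
(no background G within bulge/loop reach of a tract) and a minimum 20-bp
gap (no loop can bridge two plants). By construction, recall is 100% and
every hit is a plant — which is exactly what it is for: auditing the
scanner, not imitating genomes. Real genomes have correlated composition,
repeats, and PQS with C-containing loops; passing these tests therefore
validates the motif grammar and coordinate bookkeeping, not genome-wide hit
counts, which depend on the database grammar in ways the fixture cannot
arbitrate. The generator is fully seed-determined and restores the
caller's RNG state.

```{r synth}
g <- synth_genome(20000, c(classical = 10), seed = 7)
census <- pqs_census(find_pqs(g$record, both_strands = FALSE), g$record)
census
```

## Problem sizes and determinism

Everything in the package is deterministic given its inputs; the only
randomness is in the fixture generator, which takes an explicit seed. The
shipped test suite uses sequences of 5–60 nt for scoring properties,
enumeration-oracle folding up to 18 nt, and planted genomes of 4–100 kb;
those sizes already exercise every code path (run caps, window boundaries,
all four motif classes on both strands, degenerate folds) while keeping
the suite fast.

## Limitations

* No thermodynamics: no Tm or ΔG prediction for either fold, no
  temperature axis in the classification.
* No kinetics: conversion rates are not modelled, only flagged.
* The classifier's ladder is calibrated on one sequence family
  (single-loop C-substitutions of a parallel G4 with a 9-nt central loop);
  thresholds for other G4 topologies or loop geometries should be
  re-calibrated via the rule table.
* Motif classes cover three-tetrad G4s with the one relaxation each;
  two-tetrad G4s and i-motifs are out of scope.
* Genome-wide censuses of real genomes depend on the exact motif grammar
  of the reference database; `find_pqs()` documents its grammar precisely
  but does not claim to replicate any third-party hit list.
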