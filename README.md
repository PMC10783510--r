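# g4switch

Scoring, detection and classification of G/C-rich DNA sequences that can
switch between a **G-quadruplex (G4)** and a **hairpin** depending on the
Na⁺/K⁺ balance.

A sequence with four G-tracts (runs of ≥ 3 guanines) can fold into an
intramolecular G4, strongly stabilized by K⁺. If its loops also carry runs
of cytosines, the C-runs can instead pair with the G-tracts to form a
Watson–Crick hairpin whose stability is cation-ratio-independent. The
predominant fold is then set by the ionic conditions, which matters for
aptamer design (Na⁺-rich extracellular fluid) and for interpreting putative
quadruplex sequences (PQS) in genomes. `g4switch` implements the
computational toolkit around this competition:

* **G4Hunter scoring** — per-base run scores, mean score
  `score = mean_i s_i` with `s_i = +min(L,4)` for each G in a maximal G-run
  of length `L`, `−min(L,4)` for each C in a C-run, 0 for A/T/N; plus a
  *soft* scheme replacing the per-C penalty in C-runs of length ≥ 3 by a
  fixed magnitude (2 or 1.5), and a sliding-window genome scan.
* **PQS detection** — four motif classes (classical; long-loop 8–15 nt;
  bulged G-tract; G-vacancy), strand-aware, greedy shortest match with
  documented class precedence; BED6 output and a census with CCC-run
  stringency filters.
* **Cytosine-run analysis** — maximal C-runs, the N statistic
  `N = (total C)/3`, and the discrete CCC-run count.
* **Hairpin capacity** — maximal nested (pseudoknot-free) G-C pairing via a
  Nussinov-style dynamic program with minimum loop length, deterministic
  traceback to dot-bracket, and stem/loop/dangle reports.
* **Phase classification** — three regimes (G4-locked / switchable /
  hairpin-locked) keyed on N and hairpin capacity, with a calibrated
  potassium threshold for switchable sequences and per-buffer fold
  predictions for the nine named Na⁺/K⁺ buffers B1–B9.
* **Fixtures** — the CEB25 oligonucleotide mutant family (`ceb_family()`)
  and seed-deterministic planted-motif synthetic genomes
  (`synth_genome()`).

## Worked example

Score and classify the CEB25 family (shipped as
`inst/extdata/ceb_oligos.fasta`, or built programmatically by
`ceb_family()`):

```r
library(g4switch)
score_table(ceb_family())
```

```
    id length  scheme score total_c n_stat ccc_runs
 CEBwt     26 classic  1.50       0   0.00        0
CEBm0A     26 classic  1.38       0   0.00        0
CEBm0T     26 classic  1.38       0   0.00        0
 CEBm1     26 classic  1.12       3   1.00        1
 CEBm2     26 classic  1.04       4   1.33        1
 CEBm3     26 classic  0.92       5   1.67        1
 CEBm4     26 classic  0.69       6   2.00        2
 CEBm5     30 classic  0.30       9   3.00        3
 CEBm6     34 classic  0.32       9   3.00        3
 CEBm7     34 classic  0.00      12   4.00        4
```

The score falls as cytosines are introduced into the central loop (C-runs
are penalized), and N rises from 0 to 4. Classification turns these
features into a fold call:

```r
classify_table(ceb_family(), buffers = ceb_buffers()[c("B1", "B5", "B9")])
```

```
    id         regime k_threshold_mM n_stat ccc_runs max_gc_pairs g4hunter      B1      B5      B9
 CEBwt      g4_locked              0   0.00        0            0     1.50      G4      G4      G4
CEBm0A      g4_locked              0   0.00        0            0     1.38      G4      G4      G4
CEBm0T      g4_locked              0   0.00        0            0     1.38      G4      G4      G4
 CEBm1      g4_locked              0   1.00        1            3     1.12      G4      G4      G4
 CEBm2     switchable             15   1.33        1            4     1.04 Hairpin      G4      G4
 CEBm3     switchable             25   1.67        1            5     0.92 Hairpin      G4      G4
 CEBm4     switchable             40   2.00        2            6     0.69 Hairpin      G4      G4
 CEBm5 hairpin_locked            Inf   3.00        3            9     0.30 Hairpin Hairpin Hairpin
 CEBm6 hairpin_locked            Inf   3.00        3            9     0.32 Hairpin Hairpin Hairpin
 CEBm7 hairpin_locked            Inf   4.00        4           12     0.00 Hairpin Hairpin Hairpin
```

Up to one CCC's worth of cytosines (N ≤ 1) the G4 predominates in every
buffer; at N = 1.33–2 the sequence is a switch whose G4 appears above a
potassium threshold (15/25/40 mM; CEBm4 folds as a hairpin in B1, 0 mM K⁺,
and as a G4 from B5 on, 40 mM K⁺); from N = 3 the hairpin wins everywhere —
CEBm5 can recruit up to 9 G-C base pairs, its full composition bound:

```r
max_hairpin_pairs(ceb_family()[[8]], min_loop = 1)
#> <hairpin_fold> CEBm5: 9 G-C pairs (min_loop 1)
#>   AAGGGTGGGTCCCACCCTGGGTGGGTCCCA
#>   ..(((.(((.))).(((.....))).))).
```

A command-line interface wraps the same functions
(`inst/cli/g4switch score|scan|pqs|census|crun|hairpin|classify|fixtures`),
reading FASTA and writing TSV or BED.

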