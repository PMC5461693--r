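---
title: "Sequence and thermodynamic features for sgRNA on-target efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence and thermodynamic features for sgRNA on-target efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdesign)
```

## The problem

CRISPR/Cas9 knockout screens depend on guide RNAs that cut their target
efficiently. Efficiency varies strongly between guides targeting the same
gene, and much of that variation is encoded in the target sequence itself.
`sgdesign` treats efficiency prediction as a binary classification problem
over a 40 bp genomic window around the protospacer: 10 nt of 5' flank, a
20 nt spacer, the NGG PAM, and 7 nt of 3' flank. All coordinates in the
package are 1-based; the PAM GG always sits at positions 32–33 of the 40 bp
window, and those two fixed positions are excluded from every positional
encoding because they carry no information. For 19 nt spacers the layout is
PAM-anchored (the spacer occupies positions 12–30), a choice we make because
PAM-proximal sequence dominates every feature class here; the alternative
(5'-anchored) layout would shift the flank boundary instead. A reduced
30 bp window (4 nt flank + spacer + NGG + 3 nt flank) is also supported.

## The eight feature classes

1. **PD Mono** — binary indicator of each base at each retained position
   (38 × 4 = 152 features).
2. **PD Dinuc** — indicator of each dinucleotide at each retained start.
   Starts 31–33 overlap the fixed GG and are dropped, the strictest reading
   of "exclude the PAM GG"; 36 × 16 = 576 features.
3. **Freq** — spacer mono- and dinucleotide frequencies. Dinucleotides are
   counted over overlapping windows with denominator L − 1, so both the four
   mononucleotide and the sixteen dinucleotide frequencies each sum to one.
4. **Thermo** — nine spacer scalars: melting temperature
   (Tm = 81.5 + 16.6·log10[Na+] + 0.41·%GC − 600/L, °C, [Na+] = 0.2 M by
   default), GC fraction, and nearest-neighbor duplex ΔH (kcal/mol),
   ΔS (cal/(mol·K)) and ΔG37 (kcal/mol) including both terminal initiation
   terms and the symmetry correction for self-complementary sequences;
   plus four secondary-structure scalars: longest homopolymer run (polyN),
   longest repeated substring (repeat), longest perfect stem-loop arm (LSL,
   loop gap 3–10 nt), and minimum folding energy (MEF, kcal/mol, ≤ 0).
5. **Packer** — min/max/avg of four dinucleotide geometry scales (roll,
   twist, slide, shift) and two tetranucleotide scales (energy,
   flexibility) over the spacer; 18 features.
6. **PhyChem** — min/max/avg of twelve dinucleotide physiochemical scales;
   36 features.
7. **PseKNC** — pseudo k-tuple nucleotide composition: the 4^k overlapping
   k-tuple frequencies augmented with λ lag-correlation terms
   θ_j = mean over positions and properties of squared differences of
   dinucleotide property scores at lag j, weighted by w and normalized so
   the whole vector sums to 1. Defaults k = 2, λ = 1, w = 0.5 (17
   features); `select_pseknc_params()` re-derives the choice by 3-fold
   cross-validated AUC over a (k, λ, w) grid with ties broken toward the
   smallest parameters.
8. **Align** — Needleman–Wunsch global alignment scores between the
   PAM-proximal k-suffix of the spacer (the seed, k = 5…L) and the sgRNA
   scaffold; 16 features for a 20 nt spacer. Default scoring is match +1,
   mismatch −1, linear gap −1 — deliberately simple and fully configurable,
   since no canonical scheme exists for this comparison. The shipped
   scaffold is the standard SpCas9 tracrRNA-derived constant region
   (DNA alphabet); it is a package default, not a measured quantity, and
   can be replaced by any FASTA.

With all classes joined, a 20 nt-spacer dataset yields 844 features.

## Numerical and resource choices

**Nearest-neighbor parameters.** The duplex table is the unified
oligonucleotide nearest-neighbor set (SantaLucia 1998). The printed ΔG37
column is validated against ΔH − 310.15·ΔS/1000 within 0.05 kcal/mol per
entry at load, and the package then *uses the derived* ΔG37 rather than the
printed one: per-step print rounding (up to ~0.015 kcal/mol) would otherwise
accumulate to >0.1 kcal/mol over a 20-mer and break the internal
ΔG/ΔH/ΔS consistency that downstream consumers may rely on.

**MEF.** The folder is an intentionally small Zuker-style dynamic program:
Watson–Crick pairs only, minimum hairpin loop of 3 nt, energy = Σ stacking
ΔG37 over adjacent stacked pairs + 3.5 kcal/mol per hairpin loop, empty
structure = 0. It is exact for its own model (the test suite proves
equality with exhaustive structure enumeration up to length 12) but it is
*not* a full loop-based energy model: no bulge/internal-loop tables, no
dangles, no temperature or ion dependence. For a 20 nt spacer contributing
one scalar among hundreds of features this approximation is adequate;
anyone needing production folding energies should compute them externally
and join them as a custom column.

**repeat.** Defined as the longest substring occurring at ≥ 2 distinct
(possibly overlapping) start positions — the most literal reading of
"repetitive sequence", verified against a brute-force substring scan.

**LSL.** Reports the arm length of the longest perfect inverted repeat with
a loop gap between 3 and 10 nt (a scalar convention; palindrome scanners
typically report positions instead). Arm monotonicity (an arm of length
a + 1 implies one of length a at the same loop gap) licenses the
incremental search the implementation uses.

**Synthetic property tables.** The Packer, PhyChem and PseKNC scales are
shipped as *synthetic representative stand-ins* — realistic units, ranges
and reverse-complement strand symmetry, with the tetranucleotide energy
derived from nearest-neighbor ΔG37 sums and TT/AA pinned as the least
flexible steps — because the original published tables were not available
for transcription when the resources were built. Every file says so in its
header and carries a `synthetic_` prefix. The feature *mechanics*
(totality of the lookup, min/max/avg reduction, θ-correlations,
normalization) are exactly as specified and fully tested; only the
numerical identities of these scales are placeholders, and any user can
drop in transcribed files in the same two-column format.

**PseKNC standardization.** Property scales are standardized to mean 0 /
variance 1 over the 16 dinucleotides before entering θ (the usual PseKNC
convention); `standardized = FALSE` gives raw mode. This matters because
the six scales have wildly different units.

## The classifier and its evaluation

The predictive model is an elastic net fit with `glmnet`: binomial deviance
loss on the binary efficiency label, mixing parameter α (default 0.5 — the
midpoint between ridge and lasso; no canonical value exists for this
problem) and penalty strength chosen by 10-fold cross-validation on the
training data. Features are centered and scaled *on the training rows
only*; the scaling is stored in the fit and re-applied at prediction, so
no test-set information leaks into the model. A least-squares
(`family = "gaussian"`) mode exists for users who want the literal
squared-error objective on 0/1 labels.

Three evaluation protocols mirror how guide-design models are actually
validated: repeated 3-way cross-validation within a dataset (3 equal
stratified parts × 10 random re-splits, averaged), cross-dataset transfer
(train on one screen, test on another), and leave-one-gene-out (pool
held-out per-gene predictions, then score once — the honest estimate of
generalization to unseen genes). Operating points come from the Youden
index J = Se + Sp − 1 maximized over observed score thresholds (ties →
lowest cutpoint); paired AUC comparisons use DeLong's test for correlated
ROC curves (via pROC; self-comparison returns p = 1 by convention).
`sweep_combinations()` evaluates any subset of the 255 non-empty
feature-class combinations on identical fold assignments so that
"combination beats best singleton" comparisons are fair.

Single features are ranked two ways: by the BIC of a one-predictor
logistic regression (−2·loglik + 2·ln n; constant features reduce to the
intercept-only likelihood plus the slope penalty, non-converging fits are
flagged and ranked last) and by orientation-corrected AUC
(max(AUC, 1 − AUC)), both averaged across datasets.

## What the synthetic generator does and does not show

`generate_sgrna_data()` draws uniform-random bases, plants the PAM GG, and
draws labels from a logistic model over *the same feature definitions the
extractors compute*. Two presets define the package's reference
conditions:

* `tt-negative`: coefficient −20 on spacer TT frequency with intercept
  20/16, centering the linear predictor at zero (TT frequency has mean
  1/16 under uniform bases). This mirrors the strongest association
  reported in real screens — T/TT-rich spacers are inefficient, consistent
  with the rigidity of the TT step — and yields a Bayes-optimal AUC around
  0.76, comparable to published per-class performance.
* `pd-dinuc`: at four spacer positions, AT/TA score +1.5 and AA/TT score
  −1.5 on the linear predictor. Every mononucleotide margin is exactly
  zero by construction, so the signal is visible to position-dependent
  dinucleotide encodings and invisible to mononucleotide ones — a clean
  test bed for the qualitative ordering AUC(PD Dinuc) ≥ AUC(PD Mono).

Because the generator's effects live in the measured feature space,
parameter recovery and Bayes-bound comparisons are exact by construction.
What passing these tests does *not* show: real screens have correlated
flanking composition, chromatin context, gene-level effects and laboratory
batch structure, none of which are simulated. Synthetic results validate
the machinery, not the biology; absolute AUCs on real data will differ.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale: n = 2000
records for signal-recovery checks, n = 500 × 20 replicates for the
encoding-ordering comparison, n ≈ 1200 for the end-to-end protocol runs,
and exhaustive-enumeration oracles at sequence lengths ≤ 12–14 where
enumeration is tractable. These sizes were chosen so every statistical
claim is estimated with comfortable Monte-Carlo margin while a full run
stays interactive. Every stochastic path (generation, fold assignment,
penalty selection) takes an explicit seed and is bit-reproducible given it.

## Known limitations

* The structural/physiochemical scales are synthetic stand-ins (above);
  conclusions about *which* table-driven feature matters are therefore not
  meaningful until real tables are supplied — only the pipeline around
  them is validated.
* MEF is a reduced energy model; LSL counts only perfect-complementarity
  arms.
* No off-target scoring, genome scanning, or reverse-strand enumeration:
  input records are assumed to be protospacer-strand contexts.
* The elastic net's α is a documented default, not a tuned constant; the
  optional inner grid search is available when a dataset is large enough
  to support it.
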