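# sgdesign

Sequence, thermodynamic and structural features for CRISPR sgRNA on-target
efficiency prediction.

Guide RNAs targeting the same gene differ widely in cutting efficiency, and
much of that difference is written in the target sequence. `sgdesign`
computes eight classes of candidate features from a 40 bp genomic context
(10 nt 5' flank + 20 nt spacer + NGG PAM + 7 nt 3' flank; PAM GG fixed at
positions 32–33 and excluded from positional encodings) and models binary
efficiency with an elastic net:

| Class   | Features | Content |
|---------|---------:|---------|
| PDMono  | 152 | base indicator at each retained position |
| PDDinuc | 576 | dinucleotide indicator at each retained start |
| Freq    | 20  | spacer mono-/dinucleotide frequencies |
| Align   | 16  | Needleman–Wunsch score of the PAM-proximal seed (k = 5…20) vs. the sgRNA scaffold |
| Thermo  | 9   | Tm, GC, nearest-neighbor ΔS/ΔH/ΔG37, polyN, repeat, stem-loop arm, minimum folding energy |
| Packer  | 18  | min/max/avg of dinucleotide geometry and tetranucleotide energy/flexibility scales |
| PhyChem | 36  | min/max/avg of 12 dinucleotide physiochemical scales |
| PseKNC  | 17  | pseudo k-tuple composition (k = 2, λ = 1, w = 0.5) |

The classifier minimizes the elastic-net objective
`min_β ||y − Xβ||² + λ{α||β||₁ + (1−α)||β||²}` in its binomial-deviance
form (α = 0.5 by default, λ by 10-fold CV), and is evaluated by repeated
3-way cross-validation, cross-dataset transfer, or leave-one-gene-out,
with AUC, Youden-index operating points (J = Se + Sp − 1) and DeLong tests
for paired AUC comparisons. Single features are ranked by one-predictor
logistic BIC and by orientation-corrected AUC. A synthetic-data module
plants known sequence effects (e.g. the negative TT-frequency association
seen in real screens) so the whole pipeline is testable without external
downloads.

The Packer/PhyChem/PseKNC property tables shipped under
`inst/extdata/property_tables/` are clearly labelled **synthetic**
representative scales (see the vignette); the nearest-neighbor duplex
table carries the published unified values.

## Worked example

```r
library(sgdesign)

# 600 synthetic guides with a planted negative TT-frequency effect
ds <- generate_sgrna_data(synth_preset("tt-negative", n = 600, seed = 42))
ds
#> <sgrna_dataset 'synthetic'> 600 records, 40 bp window, 20 nt spacer (11-30), PAM N at 31
#>   labels: 310 efficient / 290 inefficient

blocks <- feature_blocks(ds, c("Freq", "Thermo"))
round(blocks$Thermo$values[1:3, ], 3)
#>             Tm  GC     dS     dH      dG polyN repeat LSL MEF
#> sg00001 52.197 0.3 -406.6 -147.4 -21.293     4      3   2   0
#> sg00002 56.297 0.4 -418.6 -151.8 -21.971     4      3   2   0
#> sg00003 60.397 0.5 -411.6 -152.3 -24.642     3      2   2   0

# repeated 3-way cross-validation of a Freq-only elastic net
run_protocol("cv3x10", ds, feature_classes = "Freq", iterations = 3, seed = 7)
#> <sg_eval cv3x10> classes: Freq
#>         auc    youden_j sensitivity specificity
#>       0.785       0.482       0.742       0.740

# which single features carry the signal?
head(rank_features_auc(ds, "Freq"), 3)
#>        feature  mean_auc flagged rank
#> 1 Freq.freq_TT 0.7788376   FALSE    1
#> 2  Freq.freq_T 0.7138765   FALSE    2
#> 3  Freq.freq_G 0.6100723   FALSE    3
```

The cross-validated AUC (0.785) sits at the planted signal's Bayes bound
(`bayes_auc(ds)` ≈ 0.78 here): the model recovers essentially all of the
available signal, and the TT frequency — the planted effect — tops the
per-feature ranking. `sweep_combinations()` evaluates any of the 255
feature-class combinations on matched folds; `fit_elastic_net()` /
`predict()` / `write_model()` cover train–serialize–score workflows, and
`inst/cli/sgdesign.R` exposes simulate/featurize/train/predict/evaluate
from a shell.

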