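# ppiboost

Sequence-only prediction of protein–protein interactions (PPIs). Most
high-confidence interaction data cover a small slice of any interactome, and
structure, domain or co-expression evidence is often unavailable —
`ppiboost` targets the setting where the primary sequences of two proteins
are the only input. It is aimed at computational biologists who want a
transparent, fully self-contained implementation of a multi-scale
physicochemical descriptor pipeline plus a from-first-principles gradient
boosting classifier, with a synthetic benchmark that exercises the whole
path without any external dataset.

## The method

**Descriptors (347 per protein).** A sequence S = s₁s₂…sₙ is encoded under
13 physicochemical channels: seven qualitative properties that partition
the 20 amino acids into three groups (hydrophobicity, normalized van der
Waals volume, polarity, polarizability, charge, secondary structure,
solvent accessibility) and six quantitative per-residue scales (H, VSC, P1,
P2, SASA, NCISC), the latter normalized to zero mean and unit sd over the
20 residues: P′ᵢⱼ = (Pᵢⱼ − P̄ⱼ)/Sⱼ. From these encodings five descriptor
families are extracted:

* amino-acid **frequency** (20),
* **composition** C, **transition** T, **distribution** D over each
  3-group encoding (7 × (3+3+15) = 147),
* **auto-covariance** AC(lag) = 1/(n−lag) Σᵢ (vᵢ − v̄)(vᵢ₊ₗₐ₉ − v̄) for
  lags 1..30 over each numeric encoding (6 × 30 = 180).

A pair (A, B) is the 694-dimensional concatenation of the two vectors.

**Classifier.** Friedman-style gradient boosting with regression trees:
f_M(x) = f₀ + ν Σₘ Tₘ(x), two-class deviance L(y, f) = log(1 + e^(−2yf)),
pseudo-residuals Rᵢ = 2yᵢ/(1 + e^(2yᵢfᵢ)), greedy CART base learners and
single-Newton-step leaf values c = ΣRᵢ / Σ|Rᵢ|(2−|Rᵢ|). The tree split
search is compiled (Rcpp); the fit is deterministic and serializes to JSON.

**Evaluation.** Stratified five-fold cross-validation with ACC,
sensitivity, precision, F-score and Matthews correlation coefficient,
reported per fold with mean ± sd.

## Worked example

Generate a synthetic benchmark with a strong planted physicochemical
signal (positive pairs join proteins of the same latent residue-usage
class), then cross-validate the full pipeline:

```r
library(ppiboost)

ds <- generate_ppi_dataset(synth_config(n_proteins = 60, n_pos = 30,
                                        n_neg = 30, effect = 3, seed = 7))
cv <- cross_validate_ppi(ds$pairs, ds$sequences, seed = 7, n_trees = 50)
cv
#> 5-fold stratified cross-validation (seed 7)
#>          acc     sn    ppv fscore    mcc
#> fold1 0.8333 0.8333 0.8333 0.8333 0.6667
#> fold2 0.6667 0.6667 0.6667 0.6667 0.3333
#> fold3 0.7500 1.0000 0.6667 0.8000 0.5774
#> fold4 0.6667 0.3333 1.0000 0.5000 0.4472
#> fold5 0.8333 0.6667 1.0000 0.8000 0.7071
#> mean  0.7500 0.7000 0.8333 0.7200 0.5463
#> sd    0.0833 0.2472 0.1667 0.1386 0.1553
```

Each fold row is the held-out performance of a model trained on the other
four folds; at this deliberately small size (60 pairs) the mean accuracy of
0.75 is well above the 0.5 chance level of the generator's negative
control, with visible fold-to-fold variance. Larger designs (400 pairs, 100
boosting rounds) reach ≈ 0.9 — see the methods vignette.

Individual descriptor values are named and inspectable:

```r
v <- protein_features(ds$sequences[[1]])
round(v[c("freq.A", "c.hydrophobicity.g3", "t.charge.g12",
          "d.polarity.g1.p50", "ac.H.lag1")], 4)
#>              freq.A c.hydrophobicity.g3        t.charge.g12
#>              0.0000              0.9231              2.2222
#>   d.polarity.g1.p50           ac.H.lag1
#>             48.3516             -0.0435
```

`freq.A` is the fraction of alanines; `c.hydrophobicity.g3` the fraction of
residues in the hydrophobic group (0.92 — this protein is from the
hydrophobic-biased class); `t.charge.g12` the percentage of adjacent
positions switching between positive and neutral charge groups;
`d.polarity.g1.p50` the percent chain position at which half of the
polarity-group-1 residues have occurred; `ac.H.lag1` the lag-1
auto-covariance of the normalized hydrophobicity profile.

A thin command-line front end over the same functions ships in
`inst/cli/ppiboost.R` (subcommands `synth`, `encode`, `train`, `predict`,
`evaluate`).

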