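# wbfs — weight-based information-theoretic feature selection

`wbfs` is an R package for filter feature selection on tabular omics-style
data: a few hundred to a few thousand samples, tens to thousands of
continuous features (protein or gene expression, spectral intensities), and
a categorical class such as a tumour subtype. It implements a weight-based
selection criterion (WBFS) that explicitly rewards *feature interaction* —
class information that only pairs of features carry — alongside the
classical information-theoretic baselines, a cross-validation benchmarking
protocol, and a planted-structure synthetic data generator with known
ground truth.

## The criterion

All criteria here are greedy forward rankers over discretized features.
Writing `I(X;Y)` for mutual information, `I(X;Y|Z)` for conditional mutual
information and `H(X)` for entropy (plug-in estimates on integer codes),
the WBFS score of a candidate `fk` given the selected set `S` and class `C`
is

    J(fk) = Σ_{fj ∈ S}  ω(fj, fk) · I(fk; C | fj)

    ω(fj, fk) = 1 + 2 · ( I(fj; C | fk) − I(fj; C) ) / ( H(fj) + H(C) )

The weight `ω` lies in `[0, 2]`: it exceeds 1 when the candidate *increases*
what an already-selected feature says about the class (positive interaction,
as in an XOR pair, which attains `ω = 2` exactly when noise-free) and falls
below 1 when the candidate makes a selected feature redundant. The second
factor `I(fk;C|fj)` is the candidate's own conditional relevance. Relevance-
only ranking (MIM) and relevance-minus-redundancy trade-offs (MIFS, mRMR,
CIFE, CONDRED, DISR) are provided behind the same interface for comparison.

## Worked example

Plant 3 informative binary features, 6 noisy duplicates of them, and 6 pure
noise features around a binary class, then rank with WBFS and with
relevance-only MIM:

```r
library(wbfs)

sim  <- generate_synthetic(synthetic_spec(
  600, n_relevant = 3, flip_probability = 0.25,
  n_redundant = 6, duplicate_noise = 0.02, n_noise = 6, seed = 11))
disc <- discretize_table(sim$table, bins = 2)

select_features(disc, "wbfs", K = 3)$selected
#> [1] "rel3" "rel1" "rel2"
select_features(disc, "mim", K = 3)$selected
#> [1] "rel3" "red6" "rel1"
```

WBFS recovers the three distinct informative features; MIM wastes its
second slot on `red6`, a near-copy of `rel3` with equally high marginal
relevance but almost no *conditional* relevance once `rel3` is in. The
difference is visible in held-out accuracy (stratified 10-fold CV, 5-NN,
matched folds):

```r
w <- evaluate_cv(sim$table, "wbfs", "knn", K = 3, folds = 10, bins = 2, seed = 11)
m <- evaluate_cv(sim$table, "mim",  "knn", K = 3, folds = 10, bins = 2, seed = 11)
w; m; compare_wtl(w, m, alpha = 0.1)
#> cv_report: wbfs + knn5, K=3, 10 folds: 82.50% +/- 3.17
#> cv_report: mim + knn5, K=3, 10 folds: 72.83% +/- 5.99
#> wbfs vs mim: Win (p = 0.000593, mean diff = +0.0967, alpha = 0.1)
```

`82.50` is the mean held-out accuracy in percent across the ten folds,
`+/- 3.17` its standard deviation; `Win` means the paired two-sided t-test
on per-fold accuracies favours WBFS at the 0.1 level.

The eight-row toy table in `?select_features` shows the interaction
machinery in isolation: with a class equal to `f1 XOR f2` and a weakly
informative `f3`, WBFS ranks `(f3, f1, f2)` with step scores
`0.189, 0.408, 2.138` bits — the last step scoring the XOR partner with the
extreme weight `ω = 2`.

## Command line

A thin launcher wraps the same functions:

```sh
Rscript inst/cli/wbfs.R select    --input data.csv --target class --method wbfs \
                                  --k 15 --mode benchmark --out ranking.tsv
Rscript inst/cli/wbfs.R benchmark --input data.csv --target class \
                                  --methods wbfs,mim,mrmr --classifiers knn,nbc \
                                  --k 15 --folds 10 --alpha 0.1 --seed 1 \
                                  --out report.json --summary summary.tsv
Rscript inst/cli/wbfs.R curve     --input data.csv --target class --kmax 30 --out curve.tsv
Rscript inst/cli/wbfs.R simulate  --n 1000 --xor-pairs 1 --noise 20 --seed 1 \
                                  --out sim.csv --truth truth.json
```

`--mode expression` switches the equal-width discretization from the 5-bin
benchmark convention to the 3-bin convention for expression data. Options
can also be given in a flat YAML file via `--config`; explicit flags win.

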