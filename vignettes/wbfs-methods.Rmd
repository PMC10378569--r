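---
title: "Weighted conditional-relevance feature selection: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted conditional-relevance feature selection: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbfs)
```

## The selection problem

Given a table of `n` samples, `m` discretized features `F = {f1, ..., fm}`
and a categorical class `C`, a filter method orders the features by a score
computed from the data alone and keeps a prefix. Purely relevance-driven
scores (the mutual information `I(f;C)`) ignore two structures that matter
in omics panels: *redundancy* — several near-copies of the same signal all
look individually strong — and *interaction* — features that are useless
alone but informative jointly, the extreme case being a pair whose XOR
equals the class.

## The weighted criterion

All quantities are plug-in estimates from empirical frequencies of the
contingency table, with `0 · log 0 := 0`. The greedy forward procedure
first selects `argmax_f I(f;C)`. Each later step scores every remaining
candidate `fk` as

$$J(f_k) \;=\; \sum_{f_j \in S} \omega(f_j, f_k)\; I(f_k; C \mid f_j),
\qquad
\omega(f_j, f_k) \;=\; 1 + \frac{2\,\bigl(I(f_j;C\mid f_k) - I(f_j;C)\bigr)}
                                 {H(f_j) + H(C)},$$

and appends the argmax. The conditional relevance `I(fk;C|fj)` already
discounts what `fj` covers; the weight `ω` additionally asks what the
candidate does *for* the selected feature. Since
`0 ≤ I(fj;C), I(fj;C|fk) ≤ min(H(fj), H(C))`, the normalised difference
lies in `[-1, 1]` and `ω` in `[0, 2]`. We use the closed upper bound: a
noise-free XOR pair (`C = fj XOR fk`, parents independent and balanced)
gives `I(fj;C) = 0` and `I(fj;C|fk) = H(fj) = H(C)`, so `ω = 2` is attained
exactly, and the package treats 2 as a reachable extreme rather than an
open bound. The weight is a ratio of information quantities and therefore
independent of the logarithm base.

The baselines behind the same interface are the standard linear family:
MIM (`I(fk;C)`), MIFS (`I(fk;C) − β Σ I(fk;fj)`, `β = 1` by default), mRMR
(mean-normalised redundancy), CIFE (redundancy and conditional redundancy
both at weight 1), CONDRED (`I(fk;C) + Σ I(fk;fj|C)`), and DISR
(`Σ I((fk,fj);C) / H(fk,fj,C)`, the pairwise joint relevance normalised by
the three-variable joint entropy). CONDRED and DISR exist in several
algebraic variants in the literature; the forms above are the canonical
ones, chosen once and frozen. With `S` empty every sum is empty, so all
criteria share the relevance-maximising first step — a useful invariant the
tests rely on.

Every (selected, candidate) pair's terms are computed once, when the
selected feature enters `S`, and folded into a running score per candidate;
ranking `K` features therefore costs `O(K · m · n)` estimator evaluations.

## Estimators and numerical conventions

* Joint quantities pair integer codes into a single compact code and reuse
  the entropy identity, e.g. `I(X;Y|Z) = H(X,Z) + H(Y,Z) − H(Z) − H(X,Y,Z)`;
  for plug-in estimates this equals the stratified per-`z` mutual
  information sum exactly. The test suite checks both routes against a
  cell-by-cell contingency oracle at `1e-12`.
* MI and CMI are clamped at zero: the identities can return `−1e-16` from
  floating-point cancellation, and downstream scores assume nonnegativity.
* `ω` at the degenerate denominator `H(fj) + H(C) = 0` (both constant) is
  defined as the neutral 1; every information term is zero there and `0/0`
  would otherwise propagate.
* No small-sample bias correction is applied: the estimates are raw
  plug-in values. All estimators accept a `base` argument, default 2
  (bits); selected orders are base-invariant.
* Tie-breaking: candidate scores within a relative `1e-9` of the step
  maximum are treated as equal and the lowest original column index wins.
  Exact mathematical ties occur routinely (e.g. features with identical
  contingency patterns, or all-zero scores after a perfect predictor), and
  a tolerance rather than exact float equality keeps the order identical
  across logarithm bases.

## Preprocessing and discretization

Protein-expression tables carry missing values. `filter_missing()` drops a
feature only when its missing fraction strictly exceeds the threshold
(default 0.5, so "half missing" survives), and `impute_mean()` replaces
each remaining hole with the feature's observed mean — per feature, not
global, since panel intensities live on feature-specific scales.

`fit_equal_width()` spans each feature's observed range with equally wide
bins; 5 bins is the package's convention for continuous benchmark data and
3 bins for expression data (both CLI-settable). Binning is half-open with
an inclusive maximum, so the fitted maximum lands in the top bin and
discretization is monotone. When the model is fitted on a training split,
out-of-range test values clip to the extreme bins; on the fitting table
clipping can never occur. Class labels are coded by first appearance, which
fixes downstream tie-breaks deterministically.

## Benchmarking protocol

`evaluate_cv()` runs stratified k-fold cross-validation (default 10 folds,
i.e. 90/10 splits; per-fold class counts deviate from proportionality by at
most one sample). The protocol defaults are `K = 15` selected features and
a 5-neighbour KNN; naive Bayes (on discrete codes — its natural
representation) and an RBF-kernel SVM adapters are included, and any object
with `train`/`predict` closures plugs in. Two policy flags trade fidelity
against leakage: `fit_bins_on = "full"` reproduces protocols that
discretize the whole table up front, while the default `"train"` fits bin
edges inside each training fold; `select_on` does the same for the ranking
itself. Reported runs are deterministic given a seed.

Method pairs are compared with a paired two-sided t-test on matched
per-fold accuracies (`compare_wtl()`, default `alpha = 0.1`): pairing is
the appropriate choice when both methods saw identical partitions, and an
unpaired Welch variant is exposed for unmatched runs. Zero-variance
difference vectors are reported as Tie with an undefined p-value — a
degenerate t statistic should not manufacture a Win. The difficulty ratio
`round(N/(m·c))` (samples per arity-class cell, median arity `m`) uses
half-away-from-zero rounding.

`folds` and a repeated-run seed are separate knobs deliberately: "ten-fold,
ten times" protocols in the literature are ambiguous between one 10-fold
partition and ten of them; the package implements one partition per call
and leaves repetition to the caller's seeds.

## The synthetic generator

`generate_synthetic()` plants four structures around a uniform class:
noisy class copies (`relevant`), re-flipped duplicates of them
(`redundant`), XOR parent pairs whose members are marginally independent of
a binary class (`xor_parent`), and uniform noise. Flip probabilities are
capped at 0.5 (beyond that the labels just swap). Continuous jitter of
amplitude 0.4 — below half the unit code spacing — turns codes into
continuous values such that equal-width binning with as many bins as the
arity recovers the codes, making the discretization path testable end to
end. XOR constructions are restricted to binary classes, where the ground
truth is unambiguous.

What the generator emulates is the *dependence structure* the criterion
targets: relevance, redundancy, and pure pairwise interaction. What it does
not emulate: feature-feature correlation within the noise block, heavy
tails and batch effects of real proteomic intensities, class imbalance, or
higher-order (three-way and up) interactions. Passing tests on this
generator demonstrate that the estimators and the selection mechanics are
correct, not that the criterion wins on any particular real dataset.

Default problem sizes in the test suite — `n` up to a few thousand, `m`
up to ~25, 100 random tables of at most 8 features for the brute-force
oracle comparison, 10⁴ random triples for the weight-bound sweep, 200
generator seeds for the recovery experiment — were chosen once as the
smallest sizes at which the quantities of interest are stable.

## Known limitations

* **Greedy and relevance-anchored.** The first selected feature maximises
  marginal relevance by construction. A consequence worth stating plainly:
  when an interacting pair is hidden among features that are *all*
  marginally uninformative, no forward pass of this family reliably finds
  it — there is nothing to anchor on, and the first picks are effectively
  arbitrary. The weight mechanism detects the partner *after* one parent is
  selected (its score then exceeds any noise feature's by an order of
  magnitude), so recovery of a hidden XOR pair hinges on a parent entering
  the selected set by chance. With one pair among 20 noise features, both
  parents land in the top 3 in roughly one run in six — far better than
  relevance-only ranking (about one in thirty) but nothing like reliable
  discovery. Panels with at least one genuinely relevant anchor feature are
  the setting where the weight pays off.
* Plug-in estimates are biased upward for conditional quantities at small
  `n` and large arities; the ratio `N/(m·c)` is a rough guide to when
  estimates become unstable.
* Only discretized (categorical) estimators are provided; no
  nearest-neighbour or kernel MI estimation on raw continuous values.
* The number of selected features `K` is a user choice; the package ranks
  and evaluates but does not auto-select `K`.
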