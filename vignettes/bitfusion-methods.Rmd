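---
title: "Bit-fusion ensemble classification: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-fusion ensemble classification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic generators do and do not emulate, the
numerical choices made at genuinely open points, and the limitations we know
about.

## The model

An ensemble of `l` base classifiers emits, for every instance, a soft class
support vector in $[0,1]^p$ over the $p$ classes; supports for one instance
stack into a $p \times l$ slice $\xi$, and a dataset into an
$n \times p \times l$ tensor. The bit-fusion combiner is a trainable
threshold unit over this slice:

1. **Activation.** $F = \xi \odot wt$, elementwise, with a $p \times l$
   weight matrix. The elementwise reading is forced by shape: the weight
   matrix is $|\omega| \times l$ and the thresholding step compares a
   $p \times l$ array against a scalar, so any contracting inner product
   would discard structure the next step needs.
2. **Binarization.** $B = [F > \delta]$ with a strict inequality; an
   activation exactly at $\delta$ yields no bit.
3. **Learning.** The target pattern $\Omega$ places ones on the true-class
   row across all $l$ columns. The error $E$ drives the multiplicative
   online update $wt \leftarrow wt\,(1 + \eta\mu E / n)$, one instance at a
   time in dataset order, for a fixed number of epochs. We record the
   per-epoch trace $\varphi$ as the mean over instances of the mean squared
   entry of $E$; the method's original mean-square expression is not
   dimensionally coherent as printed, and the mean-of-squared-bit-errors
   reading preserves exactly the intended behaviour (a nonnegative,
   typically decreasing trace).
4. **Prediction.** Per-class bit counts $\sum_j B_{ij}$, argmax wins.

Two structural facts about the update matter for everything below. It is
*multiplicative in the weight*: a zero weight is a fixed point, and whenever
$\eta\mu/n < 1$ no weight can change sign. And on the true-class row the
error is never negative, so positive true-class weights grow until their
bits fire while *negative weights are pushed further from the threshold and
can never produce a bit*. With the standard initialization (i.i.d. uniform
on $[-0.5, 0.5]$) roughly half of the $p \times l$ class–classifier
channels are therefore permanently unable to fire. This is intrinsic to the
update rule, not an implementation artifact, and it motivates both the
fallback chain and the error-sign option discussed next.

## Error sign and parameter regimes

The published update subtracts the target from the output
(`error_sign = "output_minus_target"`). From a fresh start all bits are
zero, so that
sign *shrinks* true-class weights; with $\delta = 0.9$ and supports bounded
by 1, no activation can then ever cross the threshold and the combiner
degenerates into its fallback chain. The package therefore also implements
the conventional perceptron orientation (`"target_minus_output"`), under
which under-firing true-class channels grow toward the threshold and
over-firing wrong-row channels shrink. Both options are first-class and the
choice is recorded in every run manifest.

Two constant sets are published for $(\eta, \mu)$: global constants
$(0.71, 10^{-5})$, and per-dataset tunings with $\eta \in [0.1, 0.6]$,
$\mu \in [0.1, 0.5]$. At $\eta\mu \approx 7\times 10^{-6}$ and $n$ in the
hundreds, a hundred epochs multiply a weight by at most
$\exp(100\,\eta\mu) \approx 1.0007$ — weights effectively never move, which
is why the global constants ship as the `"reference"` regime (faithful
replication) rather than the default. The default `"benchmark"` regime uses
$\eta = 0.5$, $\mu = 0.2$ (a published per-dataset tuning) with the
trainable sign; under it, a persistently pushed weight grows by roughly
$\exp(\eta\mu\,\mathrm{epochs}/p)$, enough for bits to fire within the
100-epoch budget at realistic $n$.

Remaining defaults: $\delta = 0.9$ (a reliability threshold deliberately
near 1), 100 epochs, weights uniform on $[-0.5, 0.5]$. All are the
published constants and are exposed in `fusion_config()`.

## The fallback chain

Nothing in the published rule decides an instance whose bit matrix is all
zero or whose top bit count ties — a state that provably occurs (it is the
*initial* state under $\delta = 0.9$). The package resolves this with a
fixed, ordered, per-instance-reported chain:

1. bit count (unique, nonzero maximum);
2. magnitude-weighted support sum $\sum_j \xi_{ij}\,|wt_{ij}|$, deciding
   only on a strictly positive unique maximum;
3. majority vote of the base classifiers' crisp labels (unique maximum);
4. lowest class index among the tied vote leaders.

Stage 2 uses weight *magnitudes* deliberately. Polarity already acted in
stage 1 by gating which channels may fire; reusing signed weights in a
ranking sum would let channels that training has merely disabled cast
arbitrarily large *negative* votes. Concretely, a unanimous hard-voting
ensemble must never be overruled — with signed weights and two classes, a
negative true-class row sum loses to an exactly-zero row; with magnitudes
the unanimous class holds the only nonzero sum. That unanimity guarantee is
asserted over 500 randomized trials in the test suite.

## Base classifiers and the stacking discipline

The five standard base learners are wrapped behind one spec/fit/predict
surface (`base_spec()`, `fit_base()`, `predict_soft()`): Gaussian naive
Bayes and the RBF-SVM from **e1071** (the SVM's soft supports via
pairwise-coupled probability calibration; grids $C \in 2^{-5..5}$,
$\gamma \in 2^{-15..-1}$ searchable by inner cross-validation), CART with
the Gini criterion from **rpart** grown nearly unpruned, 10-nearest
neighbours with Euclidean vote fractions via **caret**'s `knn3`, and a
single-hidden-layer MLP from **nnet** with
$\max(4, \lceil (m+p)/2 \rceil)$ hidden units. Where a published
hyperparameter has no counterpart in the underlying optimizer (the MLP's
learning-rate/momentum pair under a quasi-Newton fit), the spec fields are
accepted for configuration compatibility and the mapping is documented in
`?base_spec`. Argmax ties anywhere resolve to the lowest class index — one
rule used consistently across classifiers and combiners.

Supports used to *train* the combiner are, by default, out-of-fold: an
internal stratified 5-fold split ensures no instance's supports come from a
model that saw it. Resubstitution supports are available
(`stacking = "resubstitution"`) for literal replication, and the test suite
demonstrates the two differ exactly where they should (an overfit tree).
Likewise min-max scaling and PCA are fit on training folds only and applied
to test folds; the alternative leaks information and silently flatters
every method.

## Preprocessing choices

Min-max scaling maps each training column's range to $[0,1]$; a constant
column maps to all zeros with a warning rather than dividing by zero. PCA
mean-centers by default and decomposes the $1/n$ covariance; the raw
second-moment variant (no centering) is available as `center = FALSE`
because the method's printed construction omits the centering term.
Components retained default to a 0.95 cumulative eigenvalue fraction, the
retained dimension never being stated in the original description.
Eigenvector signs follow the convention that each vector's
largest-magnitude component is positive, making decompositions
reproducible across platforms.

## Synthetic generators: what they emulate, and what they do not

`make_gaussian_dataset()` draws $p$ isotropic unit-variance Gaussian
clusters with centroids on a regular simplex scaled to a chosen pairwise
`separation` (in units of within-class standard deviation), classes
balanced to within one instance. It emulates the *difficulty axis* of small
benchmark tables — how separated the classes are — with deterministic
geometry and no other structure.

`make_synthetic_xi()` skips classifiers entirely and draws raw support
tensors: per classifier, the winning class is the truth with the requested
probability, else a uniform wrong class; a shared latent coin with weight
`correlation` makes classifiers err on the same instances; soft slices are
Dirichlet draws with concentration 10 on the winner and 1 elsewhere (fixed,
so slices stay realistically peaked), the winner guaranteed to be the slice
maximum.

Neither generator reproduces real data's correlated features, class
imbalance, label noise, heavy tails, or classifier-specific bias patterns;
errors here are (conditionally) uniform over wrong classes. Passing tests
on these generators therefore establish the *mechanics* of the method —
exact arithmetic, invariants, ensemble value under controlled noise — not
performance claims on any real dataset.

## Problem sizes

The shipped studies use sizes chosen to make their statistical claims
stable at interactive cost: the Gaussian benchmark uses $n = 300$,
$p = 3$, $d = 5$, separation 8 under 10-fold cross-validation; the
raw-support committee study uses $n = 5000$ slices from $l = 5$ classifiers
at accuracy 0.7; concentration checks use $n = 10^4$. Binomial noise on an
accuracy estimated from 5000 draws is about $\pm 0.7$ points at one
standard error, comfortably inside the margins the studies assert.

## Known limitations

- **Dead channels.** As derived above, about half the class–classifier
  channels can never fire a bit. On well-separated data this is nearly
  harmless (the benchmark study reaches sub-1% error), and at moderate
  overlap the trained combiner can beat each base classifier and the
  classical rules (the README example). But when supports are noisy and
  individually weak, bit counting works with a random censored subset of
  the committee, and the acceptance script's committee study shows the
  combiner trailing plain majority voting by several points there. A
  committee rule that discards half its members' votes at random cannot
  match the full Condorcet effect; we document this rather than altering
  the published initialization or update.
- **No convergence theory.** Training runs a fixed epoch budget; the trace
  $\varphi$ is reported, not tested for convergence, and no stopping rule
  is applied.
- **Baselines are reconstructions.** The comparison rules implement the
  standard literature definitions; published benchmark tables for named
  implementations are comparable only qualitatively.
- **Scope.** No missing-value handling, no categorical features beyond the
  label, no streaming input, no significance testing across datasets.
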