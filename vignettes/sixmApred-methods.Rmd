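---
title: "Methods: encoding, models, and evaluation in sixmApred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding, models, and evaluation in sixmApred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmApred)
```

## The problem

N6-methyladenosine (6mA) is an epigenetic mark on adenine. Experimental
mapping (e.g. MeRIP-seq) is costly, so sequence-based classifiers are used
to triage candidate sites. The standard formulation, which this package
implements, is binary classification of fixed-length nucleotide windows
centred on an adenine: 41-nt windows whose central A is methylated
(positives) versus experimentally validated non-methylated centred adenines
(negatives), in equal numbers per species. Because benchmarks mix
DNA-alphabet and RNA-alphabet species, T and U are treated as the same base
everywhere; `normalize_alphabet()` converts explicitly and every encoder is
invariant under the conversion.

## Sequence validation

`validate_benchmark()` enforces the two structural facts of this benchmark
family: one common window length, and adenine at the centre position,
defined as 1-based index (L+1)/2. The centre is only defined for odd L, so
even-length sets pass validation only with the centre check disabled; the
check is configurable because published window lengths vary between the
41-nt construction rule and the shorter per-species example windows.
Lowercase input is accepted and uppercased; IUPAC ambiguity codes are
rejected rather than masked, because a masked base would silently distort
every frequency-based feature. Similarity-based redundancy removal (CD-HIT
at 80%) is an upstream, external step and is out of scope here.

## Encodings

Five families, all over base order A, C, G, T(U):

* **binary** — one 4-entry indicator block per position (4L features).
* **Kmer** — frequency of each k-mer among the L−k+1 overlapping windows.
  The denominator is the window count, not 4^k, so the vector sums to 1.
* **ENAC** — a width-w window slides in steps of 1 (no partial windows);
  each window contributes its internal base frequencies (denominator w).
* **CKSNAP** — for each gap g = 0..k, the 16 ordered pairs (s_i, s_{i+g+1})
  are counted over the L−g−1 available pairs and normalised by that count.
  The parameter k concatenates all gaps 0..k (16(k+1) features), following
  the convention of the iLearn-style encoding toolkits; a single-gap vector
  is available off-grid by encoding with the desired gap as the maximum and
  slicing its block.
* **NCP** — the chemical-property triples A=(1,1,1), C=(0,1,0), G=(1,0,0),
  U/T=(0,0,1), reflecting ring structure, hydrogen bonding and chemical
  functionality.

The canonical comparison grid (`enumerate_schemes()`) is binary; Kmer
k=2..5; ENAC w=2..5; CKSNAP k=1..5; NCP — fifteen schemes. Feature values
are raw frequencies/indicators in double precision; no standardization is
applied before modelling. Pair and k-mer features are ordered
lexicographically, which also matches the printed 16-pair CKSNAP order.
The exact column order of the one-hot block is not fixed by the published
description (the defining example is only available as an image), so the
A,C,G,T(U) convention here is a declared design choice.

## Classifiers

**Logistic regression** minimises
`sum_i log(1 + exp(-y_i eta_i)) + ||w||^2 / (2C)` with an unpenalised
intercept — the usual inverse-regularization parameterisation in which the
tuned value C = 11.29 is quoted. Optimisation is L-BFGS from a zero start
with an iteration cap of `max_iter`, which makes fitting fully
deterministic. The tuned configuration also names the "saga" solver; saga
is a stochastic optimiser of the same convex objective, so the solver label
is carried as spec metadata while one deterministic optimizer does the
work. For the convex, low-dimensional problems here the two reach the same
optimum up to tolerance; this substitution is a deliberate design choice,
made because no saga implementation exists in the supported dependency set.

**Random forest** is implemented in compiled code inside the package (no
random-forest dependency exists in the supported environment): fully grown
CART trees on bootstrap resamples, Gini-impurity splits with midpoint
thresholds, and `max_features` candidate features per split ("sqrt",
"log2", "all", or a fraction). The positive-class score is the fraction of
trees voting positive (a tree with a tied impure leaf contributes ½). The
forest uses its own seeded RNG stream, so fits are bit-reproducible across
platforms and independent of R's global RNG state.

Untuned ("default") configurations are the conventional library defaults
the source workflow would have used implicitly: LR C=1, max_iter=100,
lbfgs; RF 100 trees, sqrt features. Tuned configurations are LR(C=11.29,
max_iter=2500, saga) and RF(1000 trees, sqrt features).

**Randomized search** (`randomized_search()`) samples hyperparameter points
and scores each by mean cross-validated accuracy. The published description
does not state the search space, budget, or scoring metric; the declared
choices are: LR — C log-uniform on [1e-2, 1e3], max_iter in {500, 1000,
2500, 5000}, solver in {saga, lbfgs}; RF — n_estimators in {100, 250, 500,
1000}, max_features in {sqrt, log2, 0.5}; 25 points by default; accuracy as
the scoring metric because it is the headline metric of the comparison
tables. Both spaces contain the winning tuned points.

## Evaluation

Hard labels are scores thresholded at 0.5 — with balanced classes that is
the natural operating point, and no other threshold is published; a score
of exactly 0.5 goes to the negative class. Metrics are computed from the
2×2 confusion table by their closed forms; a metric whose denominator is
zero is reported as 0 with an explicit `degenerate` flag rather than NaN,
so every report is serializable. AUC is the rank-based (Mann–Whitney)
estimator with ties counted ½, computed from the continuous scores, never
from thresholded labels.

Cross-validation is stratified: each class is shuffled under the seed and
dealt round-robin into k folds, so per-class fold counts differ by at most
one and folds tile the data exactly once. The aggregate is the unweighted
mean of per-fold metrics; whether the published single numbers are
fold-averaged or pooled is not stated, so a pooled-counts mode is available
behind `aggregate = "pooled"`.

Cross-species transfer fits once on all of species A and evaluates once on
all of species B, after normalizing both to one alphabet. Positional
schemes (binary, ENAC, NCP) require equal window lengths; composition
schemes (Kmer, CKSNAP) do not.

## The synthetic benchmark generator

`generate_benchmark()` emulates the structural facts of the real
benchmarks: balanced classes, fixed odd length with a centred A, negatives
drawn i.i.d. from a background composition, and positives drawn from a
position weight matrix that mixes a fixed consensus preference with the
background at weight `signal` within ±`motif_halfwidth` of the centre.
Defaults: 400 sequences per class (the scale of the smaller published
species sets), L = 41, uniform background, halfwidth 3, signal 0.8 — strong
enough that a competent classifier should approach the published
performance range, while signal 0 is an exact null. The default consensus
is a fixed DRACH-like arrangement (GGA upstream, CTT downstream); the real
m6A consensus motif is named but not printed in the source description, so
the fixture consensus is arbitrary by design.

`generate_species_pair()` draws two random motif preferences and
interpolates species B's toward species A's by `1 − divergence`, giving a
continuous axis from identical motifs (divergence 0) to independent ones
(divergence 1) for transfer experiments.

What the generator does **not** emulate: species-specific background
composition gradients along the window, homology/redundancy structure
among sequences, and the real (unpublished) m6A consensus. A green
signal-recovery test therefore establishes that the pipeline can extract a
positional signal of realistic strength — not that it reproduces published
accuracies on real data, which require the external benchmark download.

One numerical caveat observed at desk scale: cross-validated accuracy on
null data (signal 0) is not exactly binomial around 0.5 — CV induces a
slight pessimistic bias because training and test folds are negatively
correlated — so null accuracies sit near, and occasionally just below, the
nominal 99% binomial band. The fixed-seed acceptance check accounts for
this by testing the pooled accuracy at a stated seed.

## Reproducibility

Every stochastic step (class balancing, fold assignment, fixture sampling,
bootstrap resampling, hyperparameter sampling) is governed by an explicit
seed; helpers restore the caller's RNG state, and the forest RNG is
self-contained. Pipeline runs write a manifest (config echo, seed,
versions) from which outputs are bit-reproducible; summary CSVs print
metrics at fixed six-decimal precision so reruns are byte-identical.

## Known limitations

* Published headline accuracies (e.g. RF + ENAC-2 ≈ 0.910 on *H. sapiens*)
  are computed on an external benchmark that is not redistributed here;
  they are documented for orientation, not asserted by tests.
* The saga/lbfgs solver distinction is metadata, not two optimizers.
* `max_iter` caps L-BFGS iterations; it does not emulate saga's per-sample
  iteration semantics, so "iterations" are not comparable across
  implementations (the cap is rarely binding on these problems).
* Statistical comparison between models (not part of the source analysis)
  is out of scope.
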