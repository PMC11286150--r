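---
title: "Amortized-emission HMMs for nanopore 5mC calling with incomplete k-mer training data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amortized-emission HMMs for nanopore 5mC calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gaussian-emission HMM callers for nanopore methylation assign every
*modified k-mer* — a length-6 string over {A, C, G, T, M}, where M marks a
5-methylcytosine in CpG context — its own independent current distribution.
A k-mer whose current was never observed during training therefore has no
usable emission distribution, and the caller cannot make an informed call at
any site whose pore context contains it.  For 5mC this matters little, since
k-mer complete labelled datasets exist; for rarer marks (5hmC, combinations
of modifications) they do not, and callers must *k-mer generalize*.

This package implements a hybrid solution: train the HMM as usual, then
train a small feedforward network that maps a binary featurization of the
k-mer to Gaussian emission parameters, and use it to **impute** the emission
distributions the HMM is missing.  Learned emissions are never overridden —
an ablation mode that overrides them is included and, as expected,
calls worse.  Everything runs end-to-end on synthetic nanopore signal, with
an evaluation harness that decomposes calling error into *sensor* and
*k-mer* generalization and low/high k-mer *novelty*.

## The calling model

Each aligned event (one current measurement per k-mer position per read) is
modelled as `current ~ Normal(mu(kmer), var(kmer))`.  A CpG site's 11-mer
window centred on the (hypothetically) methylated C decomposes into 6
overlapping k-mers, each containing the M.  A site call compares two
hypotheses per read:

* methylated path: the 6 k-mers of the M-window,
* unmethylated path: the same k-mers with M replaced by C,

and sums the per-read log-likelihood ratios; the site is called methylated
iff the total is positive.  Likelihoods come from a forward algorithm over
stay/step/skip transitions (`transition_params`); with no stays or skips
(the aligned-event regime, the default) the likelihood factorizes over
positions, and `call_sites()` exploits that for vectorized calling.  The
forward implementation is validated against exhaustive path enumeration on
all instance sizes up to 6 events by 6 states.

Emission training (`train_emission_table`) groups events by k-mer and uses
the sample mean and maximum-likelihood variance where at least `min_events`
events support the k-mer; every other k-mer receives a moment-pooled default
over the learned modified k-mers.  Sites lacking a confident label
(coverage below 5 reads, or any discordant per-read label) are excluded from
both training and evaluation.  The event-level alignment/update loop is
retained as an argument (`n_iterations`, default 5) but is a no-op here
because the simulator provides exact alignments.

## Featurization and the amortizer

The 141-bit featurization of a 6-mer is `[30 | 105 | 6]`:

* 30: one-hot of each position over A\<C\<G\<T\<M;
* 105: one-hot of each of the 5 adjacent dinucleotides over a 21-symbol
  vocabulary.  Of the 25 ordered pairs, MA, MC, MT and MM cannot occur in
  CpG context (M is always followed by G within the k-mer), leaving 21;
  5 × 21 = 105.
* 6: a C-or-M indicator per position, encoding that M is chemically a
  modified cytosine.

Feature order is fixed (position-major, letters A\<C\<G\<T\<M) so serialized
predictors are portable.  Trinucleotide features are deliberately absent.

The amortizer is a feedforward network with `d` ReLU hidden layers of width
`h` (grids d ∈ {3,...,6}, h ∈ {16, 32, 64, 128}), a linear output head
predicting the mean and the **log** variance (positivity by construction),
and a linear shortcut from the features to the output.  The shortcut
matters: pore-model levels are dominated by position-additive structure, so
the model starts (zero-initialized hidden output) as an additive fit and the
hidden stack learns only what additivity misses.  Without this, training
from very few k-mers (at completeness p = 5 only ~80–130 learned k-mers
exist) generalizes poorly even though a ridge fit on the same features does
well.

The loss is the symmetrized Kullback–Leibler divergence between the
predicted and target Gaussians, in closed form — a discrepancy between
distributions, not between raw parameter values.  It is invariant under a
common affine transform of both distributions, which licenses the numerical
choice of standardizing target means to zero mean/unit variance during
training (variances rescaled accordingly) and de-standardizing on output.

Optimization: full-batch Adam-style updates, peak learning rate 4e-2 with
cosine decay to zero, 1000 epochs (2000 in the parameter-recovery
experiment), decoupled weight decay 1e-3, 80/20 train/validation split.
These were selected once, in the k-mer-complete setting, by probing the
d × h grid together with learning-rate schedules, and then frozen for every
completeness level; the package default (d = 3, h = 64) is that selection.
Divergent training (non-finite loss) raises an error rather than returning
a broken predictor.

`impute_emission_table()` replaces only modified-k-mer rows whose provenance
is `default`; `override_all_emissions()` replaces all of them (the ablation
baseline); `combined_policy_call()` routes a site to a "seen" caller iff all
six of its window's modified k-mers occurred in training, else to an
"unseen" caller.

## Coherent k-mer selection

Simulating k-mer incomplete training data by deleting random modified
k-mers is physically incoherent: one methylated site pulled through the
pore yields all six of its overlapping k-mers.  Selection therefore happens
at the 11-mer window level, as an integer program: maximize the
frequency-weighted number of fully retained windows subject to a budget
`B = floor(p |S| / 100)` on unique k-mers, with the k-way AND linking each
window indicator to its six k-mer indicators.  For k = 6 the full
CpG-context modified universe has exactly 2669 members, so p = 5 gives
B = 133.

No exact MILP solver is available as an R package dependency here, so the
solver is a purpose-built exact branch-and-bound (C++): it searches window
subsets in decreasing weight-density order, pruning with a fractional
knapsack bound in which each undecided window's optimistic cost discounts
k-mers by their multiplicity among undecided windows (a valid dual bound).
Instances closed within the node cap return status `"optimal"`; otherwise
the best incumbent is returned with status `"feasible"` — never a silent
fallback.  Optimality is tested against an independent brute-force oracle
that enumerates window subsets.  A random-then-prune baseline (sample B
k-mers, keep fully covered windows) is included; coherent selection
completes many more windows at the same budget.

## The synthetic data generator

The generator emulates the statistical structure the caller consumes, not
raw squiggles.  Ground-truth mean current per k-mer = 90 pA baseline +
per-position letter effects (SD 4 pA) + adjacent-pair effects (SD 0.5 pA)
+ an i.i.d. residual (SD 0.5 pA); event noise variance is uniform on
[1, 2] pA².  Crucially, M is generated as a *perturbation of C*: its
additive effect per position is the C effect plus a methyl shift of SD
1.75 pA, and M-containing pair effects are their C-substituted counterparts
plus half-`pairwise_effect_scale` shifts (so the mononucleotide-linear
limit of the generator is exact when pairwise effects and the residual are
switched off).

The methyl-shift scale is the load-bearing parameter, and its value was
chosen by mapping the operating regimes rather than copied from anywhere:
with shifts ≳ 2.5 pA the unmethylated hypothesis is so badly violated at
methylated sites that even a flat pooled default emission calls correctly
(nothing needs imputation); with shifts ≲ 1 pA no feature-based imputer
trained on ~80 k-mers can predict means accurately enough to out-call the
default.  At 1.75 pA — within the range of bisulfite-validated CpG level
shifts for R9-era pores — the default is uninformative for unseen k-mers
while learned and imputed emissions call accurately, which is the regime
the method's real-data motivation describes.  The residual keeps
imputation imperfect at every training size; the per-k-mer variance is
drawn independently of the features and is therefore deliberately
unlearnable, bounding the achievable symmetrized KL.

References plant CG dinucleotides at spaced positions (no two CpGs within
6 bases) on an otherwise CG-free background, so every methylated site has a
valid single-M window and no k-mer ever carries two M's; overlapping-CpG
windows are out of scope.  Coordinates are 0-based half-open, single
strand.  Each site's methylation state is shared by all reads.  Reads are
contiguous intervals with uniform starts; one event per covered position
(stay/skip augmentation exists to exercise the forward algorithm).
Confident labels reuse the ≥5-read unanimous-call filter.

What the generator does **not** emulate: raw signal segmentation,
basecalling error, alignment error, strand effects, hemimethylation,
non-Gaussian current distributions, and correlated noise along a read.
Passing tests on this generator show the machinery is correct and that the
qualitative orderings hold under the stated statistical structure; they do
not certify accuracy numbers on real nanopore data.

## The evaluation protocol

`run_p_sweep()` runs, per seed and fold: select a panel from the training
folds' methylated-window frequencies at completeness p; restrict training
events to it; train the plain emission table; fit the amortizer on its
learned rows; impute; call every confidently labelled site of the held-out
fold (the test fold is never k-mer filtered); and record per-read call
error and per-site |predicted − true| methylation fraction — both are
reported because the real-data accuracy unit this protocol mirrors is
ambiguous between the two — overall, for the sensor subset (all six window
k-mers seen in training), the k-mer subset (the rest), and the low/high
novelty halves of the k-mer subset (median split on mean one-hot Hamming
distance to the unique training windows; the threshold rule is
configurable).

Class balancing and training-size normalization across p are implemented
(`balance_classes`, `normalize_training_size`) but default to off in the
sweep: they correct biases of high-capacity callers trained on site
examples, whereas the per-k-mer HMM estimates depend on per-k-mer support,
and downsampling would push k-mers below the support threshold at high p.

Desk-scale study conditions (the defaults): a 50 kb reference at CpG
density 0.04 (~2000 sites, half methylated), 30 full-length reads
(deterministic 30× coverage, so the confident-label filter retains
essentially every site and every site k-mer clears `min_events = 5` in
training folds), 3 folds in the preset used by the acceptance experiments
(6 is the general default), p ∈ {5, 10, 30, 100}, 5 seeds.  A sweep at
these sizes runs in roughly ten minutes on one CPU; all sizes are set in
`experiment_config()`.

At this genome size one desk-scale artifact deserves note: unmethylated
sites' *hypothesis* M-k-mers need never occur in training (only ~1600 of
the 2304 single-M k-mers appear among ~1000 methylated windows), so a
little imputation persists even at p = 100.  The plain and amortized
callers are therefore bit-identical at p = 100 exactly on the
no-imputation (sensor) subset; at genome scale, where each fold is
approximately k-mer complete, the subsets coincide.

## Numerical and edge-case choices

* Variance floor 1e-6 pA² on every trained or imputed emission.
* Emission defaults: moment-pooled mean/variance over learned modified
  k-mers (weighted by event support), falling back to all learned k-mers.
* Decision threshold: llr > 0 (symmetric prior); no per-read llr magnitude
  filter.
* Budgets below k are feasible but warn: no window can be completed.
* Ties in the ILP: any optimum is accepted; tests compare objectives only.
* Novelty ties: score ≤ threshold is low-novelty.
* Length-mismatched event/path sequences with no stays/skips have
  likelihood −∞ by contract.
* On-disk pore models store the standard deviation (community convention);
  the package works in variances internally and converts only at I/O.

## Known limitations

* k = 6 only for featurization (the layout is k-specific by design).
* Single modification symbol; multi-M windows rejected.
* The branch-and-bound can return `"feasible"` (best incumbent, not proven
  optimal) on large instances under its node cap; the status is always
  reported.
* The simulator's Gaussianity matches the caller's model family, so the
  sweep measures k-mer generalization, not model misspecification.
* Against the *default-emission* HMM, the amortized caller's advantage is
  not larger on high-novelty sites in this simulator (the test asserting
  that direction fails by a small, reproducible margin): the default
  caller fails roughly uniformly across novelty while imputation error
  grows with novelty.  The direction is expected to hold against learners
  whose accuracy itself collapses on novel k-mers, which is the comparison
  the novelty analysis was designed around; that comparator is outside
  this package's scope.
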