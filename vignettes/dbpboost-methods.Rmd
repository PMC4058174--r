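---
title: "Methods: physicochemical sequence features and imbalance-aware boosting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical sequence features and imbalance-aware boosting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpboost)
```

## The problem

DNA-binding proteins — transcription factors, packaging proteins,
repair enzymes — must be told apart from the rest of the proteome using
sequence alone. Two features of the problem shape this package. First,
useful signal lives in coarse physicochemical properties of the
sequence (DNA binders are, for instance, enriched in positively charged
residues), which motivates a fixed-length descriptor built from
property groupings rather than from alignments or structure. Second,
the problem is naturally *imbalanced*: curated non-binders vastly
outnumber binders, and a classifier trained naively on all of them
tends to buy specificity with sensitivity. The package couples a
188-dimensional descriptor with a boosting scheme designed to exploit,
rather than suffer from, a large negative set.

## The 188-dimensional feature vector

Let a protein sequence have length $L$ and let $o_a$ be the occurrence
count of amino acid $a$. The first block is the **composition**

$$f_a = o_a / L, \qquad a \in \{\mathrm{A}, \ldots, \mathrm{Y}\}$$

in alphabetical order (20 values summing to 1; the ordering is a
package convention, fixed once).

Each of eight physicochemical properties — hydrophobicity, normalized
van der Waals volume, polarity, polarizability, charge, surface
tension, secondary-structure propensity, solvent accessibility —
partitions the alphabet into three groups (`ctd_groupings()`). Per
property, the sequence contributes 21 values:

* **Content** (3): the fraction of residues in each group,
  $C_i / L$; the triple sums to 1.
* **Distribution** (15): for each group $i$ with $n_i$ occurrences at
  sorted positions $p_1 < \cdots < p_{n_i}$, the normalized positions
  of the first, 25%, 50%, 75% and last occurrence,
  $p_k / L$ with $k = \lceil q\, n_i \rceil$ for
  $q \in \{0.25, 0.5, 0.75\}$ and $k = 1, n_i$ at the ends.
* **Dipeptide composition** (3): counts of adjacent residue pairs that
  span two *different* groups — (1,2), (1,3), (2,3), order-insensitive
  — divided by $L$.

Concatenated: $20 + 8 \times 21 = 188$ values, all in $[0, 1]$.

### Numerical and convention choices

* **Quantile index rule.** The descriptor literature does not fix a
  rounding rule for "the 25% residue". We use
  $k = \lceil q\, n_i \rceil$ with 1-based positions: it matches the
  classic composition/transition/distribution convention, always picks
  an actual occurrence, and degenerates correctly at $n_i = 1$ (all
  five descriptors equal $p_1/L$).
* **Empty groups.** A group with no occurrences contributes five zeros;
  there is no position to report and zero keeps the block in $[0,1]$.
* **Dipeptide normalizer.** A sequence of length $L$ has $L - 1$
  adjacent pairs, yet the canonical form of this descriptor divides by
  $L$. The default follows that form; `normalizer = "pairs"` switches
  to $L - 1$ for users who prefer counts normalized by the number of
  pairs. The difference is a factor $(L-1)/L$ and does not affect any
  qualitative behaviour.
* **Hydrophobicity grouping.** One widely circulated version of the
  hydrophobicity row lists its neutral group as "GASTPHT" — a
  duplicated T, and only 19 distinct letters across the row. We
  complete it to "GASTPHY": Y is the unique letter missing from the
  row, and the completion is forced by the partition requirement every
  other row satisfies. `read_groupings()` accepts a config file for
  users who want different group definitions; every row is validated
  as a partition of the 20-letter alphabet.

A deliberately naive reference implementation in the test suite checks
the fast extractor element-wise to $10^{-12}$ over random sequences of
lengths 1–500.

## The boosting ensemble

Training data are $n$ positives $S^+$ and $l \gg n$ negatives $S^-$.
A weight distribution $W_t$ over $S^-$ starts uniform
($W_1(i) = 1/l$). Each round $t = 1, \ldots, T$:

1. draws $n$ negatives from $S^-$ with replacement, with probabilities
   $W_t$, and trains base learner $h_t$ on these plus *all* positives
   (a balanced set, so no round is dominated by the majority class);
2. scores $h_t$ on the full negative pool, giving error rate
   $\varepsilon_t$ (the fraction of $S^-$ predicted positive);
3. multiplies the weights of misclassified negatives by
   $$f_t = \log_{\,l}\!\left(l \cdot
     \frac{1 - \varepsilon_t}{\varepsilon_t}\right)$$
   and renormalizes to obtain $W_{t+1}$.

The base-$l$ logarithm is the characteristic damping of the scheme:
$f = 1$ exactly at $\varepsilon = 0.5$ (a chance-level round leaves the
distribution untouched), $f > 1$ precisely when the learner beats
chance on the negatives, and even at $\varepsilon \to 0$ the factor
stays modest ($\approx 2$ for $l$ in the hundreds), so the large
negative set is cycled through gradually instead of a few hard
negatives absorbing all the mass. $\varepsilon_t$ is clamped into
$[1/(2l),\, 1 - 1/(2l)]$ before the logarithm so the factor is finite
when a round is perfect or perfectly wrong on the negatives. Positives
carry no weights: the scheme re-weights only the sampling of the
abundant class.

Prediction is a weighted vote,
$\mathrm{score}(x) = \sum_t \alpha_t h_t(x) / \sum_t \alpha_t \in
[-1, 1]$, label $+1$ iff the score is positive. Where the scheme
itself leaves freedom we adopt:

* **Vote weights.** $\alpha_t = \ln((1 - e_t)/e_t)$ with $e_t$ the
  round learner's unweighted error on the *full* training set (clamped
  like $\varepsilon_t$, and $\alpha_t$ clamped to $[0, 10]$ so a
  single perfect-on-training round cannot drown out the rest).
  This is the standard boosting vote weight; `vote = "uniform"` is
  available for comparison.
* **Tie-break.** An exact zero score maps to the negative class — the
  majority class of the intended application, so the conservative
  call.
* **Sampling with replacement.** Well defined for any weight
  distribution, including degenerate ones.
* **Round-to-learner assignment.** Rounds cycle through the registry
  in order; the default is one pass over the 20-learner roster
  (`T = 20`).
* **Failed rounds.** A base learner that errors during fitting is
  skipped with a warning (weights carry over unchanged); training
  fails only if every round fails.

### The base-learner roster

Heterogeneity among base learners is itself a source of ensemble
strength. The default registry (`default_registry()`) spans four
families: nearest-neighbour classifiers ($k = 1, 5, 15$), a spread of
tree learners (pruned and deep CART, a binary tree, one random tree,
bagged trees, a random forest, gradient-boosted trees, a one-split
stump), simple probabilistic/linear models (naive Bayes, logistic and
penalized logistic regression, linear discriminant, a majority-class
baseline), and margin/function classifiers (linear, sigmoid and radial
SVMs, a small neural network). These are R-native implementations; no
attempt is made to mimic the internals of any other toolkit's versions
of such algorithms, and the roster is configurable (a text file with
one learner kind per line for the CLI, or any list of
`base_learner_spec()`s in R).

## Evaluation

`classification_metrics()` reports, from confusion counts
$(TP, FP, TN, FN)$: sensitivity $SE = TP/(TP+FN)$, specificity
$SP = TN/(TN+FP)$, accuracy, Matthews correlation coefficient

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}},$$

precision, recall and $F_1$. $SE$, $SP$ and $ACC$ are percentages;
$MCC$, $P$, $R$, $F_1$ fractions. A metric whose denominator is zero
(e.g. $SE$ on a test set with no positives) is reported as 0 and
flagged in the `degenerate` field rather than as `NaN`, so downstream
tables stay numeric; real benchmark evaluations never hit these cases.

## The synthetic generator

`generate_sequences()` emulates a two-class benchmark without any
external data: negatives draw each residue independently and uniformly
(1/20 per letter); positives shift total probability mass `delta` onto
a configurable enriched set, by default arginine and lysine — the
positive-charge bias of real DNA binders. Defaults were fixed once, as
a realistic emulation of curated benchmark collections in this field:
`n_pos = 146`, `n_neg = 2125` (the shape of an expanded benchmark with
a large negative surplus), lengths uniform on 50–300 residues
(domain-scale proteins), `delta = 0.3`.

What the generator does and does not emulate matters for interpreting
green tests. Residues are sampled independently, so the signal is
purely compositional: the composition and content blocks are
informative, while the distribution and dipeptide blocks carry
essentially no class signal. Tests passing on this data therefore
demonstrate that the pipeline *recovers compositional class structure
under imbalance* — they say nothing about performance on real
proteomes, where signal is weaker, homology structure exists, and the
positional blocks earn their keep. At `delta = 0.3` the synthetic
classes are strongly separable, which is why held-out metrics in the
examples saturate near 100%; the `delta = 0` control confirms that
without signal the same pipeline sits at chance.

## The negatives-sweep experiment

`split_validation()` holds out the *first* $k^+$ positives and first
$k^-$ negatives in input order as a fixed validation set — input order
is part of the protocol, so a given dataset always yields the same
split. `sweep_negatives()` then trains once per requested negative
count $n$, using all remaining positives plus the first $n$ remaining
negatives (prefixes, so smaller training sets are nested in larger
ones and the sweep isolates the effect of *more* negatives rather than
*different* negatives), and evaluates each model on the validation
set. On data with a genuine positive/negative overlap this traces the
characteristic rise-to-plateau of performance as negatives are added;
on the strongly separable synthetic default the curve is flat at
ceiling.

## Problem sizes and reproducibility

Everything stochastic — generation, per-round negative sampling, any
randomized learner — is driven by explicit integer seeds, and
identical inputs plus seeds reproduce models, predictions and sweep
tables bitwise; per-round seeds are derived deterministically from the
model seed. The test suite exercises the full pipeline at moderate
sizes chosen to probe the claims without waste: oracle equivalence on
200 random sequences (lengths 1–500), imbalance experiments at
150 positives / 1500–2200 negatives with $T = 10$ over 5 seeds, and
the bundled evaluation script at the 146/2125 benchmark shape with the
full 20-round roster.

## Limitations

* The descriptor is alignment-free and fixed-length; it cannot see
  motifs, domains or evolutionary conservation (no PSSM/profile
  features by design).
* Base learners are heterogeneous stand-ins by family; users wanting a
  specific algorithm's behaviour should supply their own registry.
* The vote-weight and tie-break conventions above are reasonable
  defaults, not the only defensible ones; both are overridable.
* Synthetic benchmarks bound what the included experiments can show
  (see above); claims about real data require real datasets, supplied
  as FASTA through the same interfaces.
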