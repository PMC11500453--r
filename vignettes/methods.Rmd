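---
title: "Methods: a deep forest cascade for imbalanced microbiome phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deep forest cascade for imbalanced microbiome phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented in `microhdf`, the assumptions
behind it, the parameters that matter, and the design decisions taken where
the architecture left genuine choices open. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` compute themselves.

## The prediction problem

The input is a samples × taxa matrix of relative abundances (rows sum to 1;
the package renormalizes unconditionally, so percentage-scaled tables work
identically) together with binary labels, 0 = control and 1 = case. Three
properties of such cohorts drive the design:

* **class imbalance** — published gut cohorts reach imbalance ratios
  (majority/minority count) of 3–4, and forests trained on them learn to
  ignore the minority class;
* **high dimensionality at small n** — hundreds of taxa against tens to a
  few hundred samples;
* **structure among features** — taxa are leaves of a taxonomy, and related
  taxa tend to shift together.

## Phylogeny-derived feature views

`build_taxonomy_tree()` turns the lineage strings into the least-pruned
taxonomy tree: each lineage is a root-to-leaf path, shared prefixes share
nodes, and single-child internal nodes are retained so that tree depth
corresponds to rank. Two templates linearize the tree:

* the **level-order template** (`level_template()`) lists *every* node
  breadth-first, root first; populated positions of internal nodes carry the
  sum of their descendant leaves' abundances, so one vector simultaneously
  encodes species-, genus-, family-, ... level aggregations
  (hierarchical consistency: each node equals the sum of its children, and
  the root equals the sample total);
* the **post-order template** (`postorder_template()`) lists the leaves in
  depth-first left-to-right order, making taxa that share ancestry adjacent.

Both `include_internal` flags are configurable; the defaults (level with
internal nodes, post-order leaves only) follow the reading that the level
view captures "every node at each level" while the post-order view
rearranges the *taxa*. How internal template positions should be filled is
not prescribed by the architecture; descendant-leaf aggregation was chosen
because it is the established convention for tree-embedded abundance
matrices and gives the level view its multi-rank interpretation.

Child order inside the tree is unspecified by any input, yet the templates
depend on it. Children are therefore sorted lexicographically by token
(C collation, locale-independent) at every node: determinism and
permutation-stability beat fidelity to an unrecoverable display order.
Trees supplied as Newick override lineage-built trees; their leaves are
matched to taxa by terminal rank token, unmatched leaves are pruned and
unmatched taxa appended under the root, each with a warning. The Newick
reader is implemented in the package because rank-aligned taxonomy trees
are chains of single-child nodes, a structure general phylogenetics parsers
do not preserve reliably.

## Forest units

**RF-CUS** rebalances classes without discarding majority-class structure.
The majority samples are clustered with affinity propagation on their
Bray–Curtis dissimilarities (similarity = −BC; damping swept over 0.5, 0.7,
0.9 and preference over the median and minimum similarity; the first
convergent run with a cluster count in [2, k], default k = 15, wins, and
K-means with k = min(15, n) is the fallback — the message-passing algorithm
is implemented in the package). Each balanced subset then draws
`m = round(u · n_majority)` majority samples *without* replacement,
allocated across clusters proportionally to cluster size with
largest-remainder rounding (every non-empty cluster contributes at least
one sample once m ≥ number of clusters), paired with `m` minority samples
drawn *with* replacement. One probability forest of `trees` trees is fitted
per subset and the `n_subsets` forests vote by unweighted averaging.

The undersampling ratio `u` is interpreted as *the fraction of the majority
class kept per subset*; this reading turns the published setting `u = 0.4`
into a single scalar (85 majority / 25 minority gives 34 + 34 per subset)
and is configurable. The number of subsets is not prescribed; the default
is `n_subsets = 10`.

**ERT** reduces dimensionality before fitting extremely randomized trees.
Features are ranked by a LEfSe-shaped LDA effect score: abundances scaled
per-million, a Kruskal–Wallis screen at α = 0.05 (non-survivors and
constant features score 0), then log10 of the averaged one-dimensional
discriminant and raw mean differences, floored at 1 so scores are
non-negative; ties in the ranking break by feature name. The subclass and
bootstrap stages of the full biomarker pipeline are deliberately omitted —
the score is used only as a ranking statistic. Sequential forward selection
then scans the ranking greedily (wrapper: a small ERT scored by internal
`sfs_cv_folds`-fold balanced accuracy), keeping a feature iff it improves
the score by more than `sfs_tol = 1e-4`, stopping after `sfs_patience = 10`
consecutive rejections or `sfs_max_scan` candidates. The selected set is
never empty (it is seeded with the top-ranked feature). Because the wrapper
estimate is stochastic, occasional chance acceptances are unavoidable at
that tolerance; the acceptance bar ratchets upward with each accepted
feature, so growth on pure-noise features self-limits at a handful of
columns — the tests assert that property rather than a literal
single-feature outcome.

## The cascade

Each layer holds four units — RF-CUS ×2 and ERT ×2, differing only by seed
stream — and outputs eight class probabilities per sample. Augmentation
always re-appends the *original* channel input:
`h_{l+1} = f_{l+1}(h_l) ‖ x`, so every layer input is (8 + original width)
columns after the first.

Two decisions here are consequential:

* **Out-of-fold augmentation.** The class vectors passed to the next layer
  are produced by units refit on an internal stratified split
  (`oof_folds = 3`), never by a unit that saw the sample — in-sample
  augmentation overfits catastrophically in a stacked ensemble. The ERT
  units' feature subsets are selected once per layer on the full layer
  input and reused across the fold refits: selection sees all layer rows,
  but the *units* producing a sample's augmented output never trained on
  that sample, and in cross-validation the entire fit — selection included —
  happens inside the training fold.
* **Channel stopping.** Channels grow until the internal validation AUC
  (computed from the out-of-fold class vectors) fails to improve for
  `layer_patience = 1` layer or `max_layers = 5` is reached, keeping the
  best-scoring depth. The two channels stop independently; their depths are
  not coupled by the architecture, and coupling them would force the weaker
  view to the stronger view's depth.

Channel A learns from the raw abundance view (`O`), channel B from the
concatenated phylogeny views (`L+P` by default — the raw view already lives
in channel A). The final layer (one plain random forest + one ERT ensemble,
averaged) consumes the concatenation of the channels' last-layer class
vectors only; a flag (`final_raw_features`) appends the raw features for
the alternative reading. Single-channel (`abundance`, `phylo`) and merged
(`merged`: one cascade on `O+L+P`) architectures are available for
ablation. Prediction thresholds the case probability at 0.5 with ties
going to control, biasing against false positives.

## Feature importance

`compute_fiv()` sums Gini impurity decrease ("information gain" in the
impurity sense used by standard forest implementations) per feature over
all trees of all forests of all layers, channels and the final layer, then
normalizes. Columns are mapped back to original feature ids: raw and
post-order positions to their taxon id (gains pooled under one id when a
taxon appears in several views), level-order internal positions to the
internal node's lineage path, and augmented probability dimensions into a
reserved `__augmented__` bucket that is excluded from the normalization
(the importance index runs over original features only) but kept for
diagnostics. A degenerate all-zero total yields a uniform distribution with
a warning.

## Synthetic data generator

`simulate_microbiome()` stands in for fitted-template simulators so that
every component is testable offline. It emulates:

* per-taxon log-normal base abundances (taxon means ~ N(0,1), per-entry
  dispersion σ, default 1);
* **detection-limit zero inflation**: the probability of a zero falls
  logistically with log-abundance, with `zero_inflation` (default 0.3) the
  dropout probability at the median log-abundance. Zeros in sequencing data
  are predominantly below-detection events, so dropout must deplete rare
  entries more than abundant ones — a label-independent uniform dropout
  would instead cap the achievable AUC well below 1 even for very large
  planted effects, which contradicts how real strong signals behave;
* planted multiplicative fold changes (`effect_size`) on
  `n_differential` taxa in case samples, applied before renormalization;
  by default the planted taxa are *sibling leaves* (consecutive species in
  a regular rank hierarchy with branching factor 3), so phylogeny views
  carry aggregated signal — a flag scatters them;
* compositional closure (every row renormalized to 1) and full determinism
  given the seed.

It does **not** emulate real-data features such as taxon-taxon correlation
beyond the hierarchy, overdispersed library-size effects, batch effects, or
fitted marginal distributions of any cohort. Passing tests on this
generator therefore demonstrates correctness and the intended qualitative
behaviors (imbalance benefit, phylogeny benefit, null calibration), not
cohort-level performance; published real-cohort scores additionally depend
on batch-effect correction, which this package expects as a preprocessing
step upstream.

## Numerical choices and degenerate inputs

* Bray–Curtis of two all-zero samples is undefined; it is reported as 0
  with a warning. All-zero *test* samples predict normally (zero row left
  unnormalized).
* Printed-precision quantities (imbalance ratio, subset size
  `round(u · n_majority)`) use round-half-up, not banker's rounding.
* AUC is the midrank statistic (equivalent to all-pairs counting with half
  credit for ties); AUPR is the precision–recall step integral with tied
  scores grouped. Recall and F1 target the case class at threshold 0.5.
* All randomness flows from one seed through named child streams
  (clustering, per-subset draws, per-forest seeds, folds), so identical
  seeds give identical models; collation-dependent orderings are pinned to
  the C locale.
* Layer fitting requires at least `oof_folds` samples per class; repeated
  CV requires at least `k` samples per class; both error explicitly.

## Problem sizes in the shipped checks

The test suite and acceptance script run the full architecture at reduced
ensemble sizes (25 trees, 3 subsets, depth 1, trimmed wrapper scans) —
every structural element is exercised, only the ensemble budgets are
scaled. Study conditions used: strong-signal and permuted-label calibration
at n = 100, D = 200 (effect 10 on 5 taxa); importance recovery of a single
10× taxon at n = 100, D = 60 over ten seeds; minority-recall comparison
against a plain 100-tree forest at imbalance ratio 4 (20 cases / 80
controls, effect 3 on 10 taxa) on shared folds; architecture ablation at
n = 100, D = 100 with twelve sibling differential taxa at effect 3, where
the comparison is informative (neither floor nor ceiling).

## Known limitations

* Binary phenotypes only; multi-class and continuous outcomes are out of
  scope.
* No batch-effect correction: cross-study inputs are expected
  pre-corrected.
* The affinity-propagation sweep is bounded rather than exhaustive; data
  for which no swept setting converges fall back to K-means by design.
* The wrapper selection is a local search over a fixed ranking; it is not
  guaranteed to find the globally best subset, and at its stated tolerance
  it admits occasional chance features (see above).
* FIV inherits the biases of impurity-based importance (preference for
  features with many distinct values, importance dilution among correlated
  taxa — mitigated, not removed, by pooling views per taxon).
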