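---
title: "Re-ranking retrosynthesis predictions with reaction-change features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-ranking retrosynthesis predictions with reaction-change features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroranker)
```

## The problem

A single-step retrosynthesis model proposes, for a product molecule, an
ordered list of candidate reactant sets. Because these models are trained on
reaction corpora dominated by a handful of very common transformations, their
rankings inherit a *frequency bias*: the recorded (ground-truth) reactants of
a rarer reaction pattern often sit at a low rank, with a confidence score
nearly tied with its neighbours and far below the head of the list. Those
low-confidence tails are exactly where a purely chemical signal can help.

`retroranker` scores each (candidate reactants, product) pair with a model
that sees only chemistry — molecular graphs plus the *potential reaction
changes* implied by the atom mapping — and then re-orders the low-confidence
part of each list. The chemical score is deliberately independent of the
upstream model's text-generation or template machinery, so it adds
information rather than re-weighting the same signal.

## Reaction-change annotation

All change information is derived from the atom map of a candidate reaction
`reactants >> product` (map numbers link product atoms to reactant atoms;
they are consumed as input, never inferred here):

* **broken bonds** — map-number pairs bonded in the reactants but not in the
  product; **formed bonds** — the reverse; **order-changed bonds** — bonded
  on both sides with different bond order. An order change counts as one
  changed bond. The three sets are disjoint by construction and their union
  size is the *changed-bond count* of the reaction, whose dataset mean
  (`mean_changed_bonds()`) is the statistic that links re-ranking gains to
  reaction classes with a larger degree of change.
* **reaction center** — every atom incident to a bond in any of the three
  sets.
* **leaving-group atoms** — reactant heavy atoms whose map number is zero or
  absent from the product. Product atoms must all be mapped into the
  reactants; an unmapped product atom is a mapping error, because in the
  retrosynthetic direction the product is the given quantity.
* **reacted-neighborhood counts** — for every atom, the number of center
  atoms within a breadth-first radius *r* of it (excluding the atom itself).
  The default radius is `r = 1` (immediate neighbours) and is exposed as a
  parameter; larger radii smear the center signal over a wider shell.

Two sides of a reaction can draw the same aromatic ring differently (aromatic
versus Kekulé notation). Both sides are therefore passed through a
conservative aromatization pass before diffing: six-membered rings with
perfectly alternating single/double bonds, and five-membered rings with two
double bonds and one saturated N/O/S member, are rewritten as aromatic. This
is intentionally narrower than a full Hückel analysis — it covers the ring
systems the package's own generator and the common benchmark chemistry
produce, and anything it declines to aromatize is simply compared as drawn.
Canonical identity testing of candidate reactant sets does *not* rely on this
pass: `canonical_candidate_key()` delegates to OpenBabel canonical SMILES
(via ChemmineOB), which performs its own perception, strips atom maps, and
makes string equality a sound recorded-match test.

Hydrogens are implicit throughout; every count is over heavy atoms.

## Featurization

Each candidate becomes a *pair* of numeric graphs: all reactant fragments
merged into one disconnected graph, and the product. Atom features
concatenate molecule-level descriptors (element one-hot over a 20-element
organic vocabulary plus an "other" bucket, degree, formal charge,
aromaticity, implicit-hydrogen count, ring membership) with change
descriptors (center flag, reacted-neighborhood count, leaving flag, and the
heavy-atom size of the leaving fragment the atom belongs to). Bond features
are order one-hot, ring flag, a conjugation flag, and a changed-bond flag.

Counts are encoded as clipped one-hots (degree 0–5, H count 0–4, reacted
neighbours 0–4+) rather than raw integers so feature scales stay bounded; the
leaving-group size is the one deliberately unbounded change feature, since
its magnitude is itself the signal. The layout is declared data — a *feature
schema* of (name, width) pairs with an MD5 hash — precisely because the
"right" feature list is an open design surface: a trained checkpoint stores
the hash and scoring refuses graphs laid out under a different schema. The
key property of the construction is that two candidates for the *same*
product share identical molecular features on the product side but differ in
the product-side change features whenever their annotations differ; that is
what lets the twin encoders tell candidates apart.

## The ranking model

Two independent encoder backbones — one for the merged reactant graph, one
for the product — run an attention-gated message-passing network: each
directed edge computes a sigmoid gate from both endpoint states and the bond
features, the gated messages are summed into a residual ReLU node update, and
a global attention readout (softmax attention over nodes, optionally
multi-head, iterated through a small tanh update for a configurable number of
steps) pools each graph into a vector. Message passing, gating and softmax
pooling are all node-order agnostic, so embeddings and scores are invariant
under atom permutations of the input — a property the test suite checks to
`1e-5` on randomly initialized models. The reaction representation is the
concatenation of the two pooled vectors, and the scorer is two affine layers
with a ReLU between, producing one scalar.

Training is pairwise: for each product with a recorded candidate, up to
`max_pairs` (recorded, non-recorded) tuples are formed — by default negatives
are re-sampled each epoch under the run seed, which spreads a small pair
budget over more of the candidate list — and the two scores are pushed apart
with a label-smoothed two-class cross-entropy: softmax over
`(s_pos, s_neg)` against the target `(1 − ε, ε)`. At equal scores the loss
is `log 2` for every `ε`; for `ε > 0` the loss is strictly decreasing in the
margin only up to `logit((1 − ε)/ε)` and rises slowly past it — that
stationary point is a mathematical property of label smoothing (it is what
stops the model from chasing unbounded margins), and the tests assert both
the monotone region and the minimiser location rather than pretending the
loss is globally monotone. Symmetric pairs obey
`L(s1, s2) + L(s2, s1) ≥ 2 log 2` with equality iff the scores are equal.

Defaults (`encoder_config()`, `train_config()`): hidden width 200, 3
message-passing layers, 2 readout steps, 1 attention head, dropout 0 (applied
to the scorer hidden layer only, training time only), `ε = 0.1`, Adam with
learning rate `1e-3`, batch 32. These are declared configuration values, not
reproductions of any published setting. Model selection is by validation
*pairwise accuracy* (fraction of validation pairs ranked correctly), not by
loss, because the downstream use is ranking. Optimization state is float
throughout; forward/backward passes are implemented in C++ and verified
against central finite differences in the test suite. Unparseable candidates
coming from an upstream beam search are retained as *unscorable* sentinels
carrying a score of `−∞`, so re-ranking is always a permutation of the
original list and top-k accuracy stays comparable.

## Re-ranking strategies

Both strategies respect the head of the original ranking and only touch the
low-confidence tail:

* **S1(p, k)** — among the `n′` candidates at original rank > k, the
  `⌊p · n′⌋` with the lowest ranking scores are moved to the end of the
  list, re-ordered by score (descending — a better score earns a better
  final position). Positions 1..k are preserved exactly.
* **S2(p, k)** — candidates are sorted by the sum of their original rank and
  their S1 rank; the original ranking weighs more than under S1, which makes
  S2 the right choice when the upstream model's head is already strong.

Three deterministic conventions close the gaps a ratio-and-sort description
leaves open. First, the demotion budget is computed over the candidates
*below* the preserved head (`⌊p · n′⌋`), not over all `n` — otherwise head
members could be selected-but-unmovable and `p` would overstate the demotion;
a `pool = "all"` switch restores the all-`n` reading. Second, score ties at
the demotion boundary are resolved in favour of *keeping* the candidate with
the better original rank. Third, every remaining tie falls back to original
rank ascending. With these rules both strategies are total functions; the
test suite checks them against independent brute-force re-implementations on
thousands of random instances with injected ties, plus exhaustive invariants
(permutation property, head preservation, `p = 0` identity, `S1(1, 0)` =
pure score sort, demotion-set monotonicity in `p`) for all list lengths up
to 7.

`p` and `k` can be set empirically or tuned with `grid_search_rerank()` on a
validation split. Evaluation reports top-k accuracy, the *final-accuracy
position* (the smallest cutoff at which accuracy stops improving up to a
maximum list length — a proxy for the per-step search space of a multi-step
planner; `rerank_predictions()` on the first-step candidate list is the
multi-step integration point this package exposes), the number of products
whose recorded rank improved, and the mean changed-bond count overall and on
the improved subset.

## The synthetic generator

Real benchmarks at meaningful scale require upstream single-step models and
GPU training, so the package ships a generator
(`generate_dataset()` / `synth_config()`) that reproduces the *structure* of
the problem at desk scale. Products are assembled from random alkyl/aryl
fragments around one of four linkages — ester, amide, secondary amine, C–C —
and the recorded reactants are produced by the inverse template as an
explicit graph rewrite, with atom maps assigned during the rewrite. Decoys
are perturbations: disconnecting a *different* site of the product
(selectivity failure), inflating the leaving group moderately or grossly,
and no-op identity candidates. The planted changed-bond counts (2 for the
heteroatom templates, 3 for C–C) are recovered exactly by the annotation
module, which makes the generator and the change detector mutual oracles.

The original ranking follows the frequency-bias model: each candidate's
upstream score is `f^β · exp(noise)`, where `f` is the frequency of its
(pseudo-)template under the template mix and β scales the bias. At `β = 0`
the recorded rank is uniform (verified by a chi-square test at 2,000
products); the default `β = 2` with the default mix (ester 0.55, amide 0.25,
amine 0.12, C–C 0.08 — a common-transformations-dominate profile, with
log-normal noise σ = 0.35 keeping near-tied neighbours) pushes the recorded
candidate of rare templates well down the list and keeps the original top-1
accuracy low by construction.

What the generator does *not* emulate: real substituent diversity,
stereochemistry, reagent/condition effects, and — most importantly — decoys
that are chemically wrong in ways invisible to change features. Wrong-site
decoys are exactly such candidates (their change statistics match the
recorded ones), which is why the *separable* study configuration used in the
recovery experiment sets their weight to zero: the experiment measures
whether the model recovers a preference that is expressible in its features,
not whether change features solve selectivity. Passing it therefore shows
the pipeline learns and transports a planted chemical preference end to end;
it does not certify performance on patent-scale data.

## Desk-scale study conditions

The standard experiment (`desk_scale_experiment()`, also what
`scripts/acceptance.R` runs) uses 2,000 training and 500 test products with
10 candidates each, the separable decoy mix, β = 2; encoder hidden width 32,
2 message-passing layers, 1 readout step; 10 training epochs with 3 pairs
per product per epoch. A full run takes a few minutes on one CPU core. Under
these conditions the original ranking's top-1 accuracy is far below 0.3, and
re-ranking with S2(1.0, 0) lifts top-1 and top-3 accuracy by well over 15
percentage points while the final-accuracy position does not increase; the
pure score order S1(1.0, 0) places the recorded candidate in the top 3 for
the large majority of held-out products. The whole pipeline run twice under
one seed produces bit-identical reports (all randomness flows through R's
RNG; the C++ kernels are deterministic).

## Numerical and degenerate-input choices

* Softmax attention subtracts the per-graph maximum before exponentiation;
  the pairwise loss uses the log-sigmoid stable form.
* A single-atom graph has no edges: message passing leaves it at its input
  projection and the readout degenerates to that node's embedding — scores
  stay finite (tested).
* Glorot-uniform initialization is drawn from R's RNG so a `set.seed()`
  fixes the whole run; seeds derived internally stay well below `2^31`.
* Empty candidate lists, rank gaps, duplicate recorded candidates and
  schema mismatches raise typed conditions (`rr_format_error`,
  `rr_usage_error`, `rr_schema_error`) rather than partially computing.
* `K_max` for the final-accuracy position must not exceed the shortest list;
  the smallest saturating cutoff is returned even when the saturating
  accuracy is zero.

## Known limitations

* The SMILES dialect is the one retrosynthesis toolchains emit (organic
  subset, bracket atoms, ring closures, branches, dots); stereo markers are
  parsed and discarded, and aromatic perception beyond the conservative ring
  pass is delegated to OpenBabel at canonicalization time only.
* The reaction-change feature list is an extension surface: the two named
  neighborhood/leaving-group features are implemented, and the schema
  mechanism exists so further features can be added without silently
  breaking trained checkpoints.
* One backbone family is provided (attention-gated message passing with
  attention readout). The encoder sits behind the `encoder_config` surface
  so a transformer-style backbone could be added; nothing in training or
  re-ranking depends on the backbone choice.
* Upstream confidences are carried through the data model but are not model
  inputs: the score is chemical by design.
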