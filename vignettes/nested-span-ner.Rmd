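---
title: "Structured span representations and constraint-guided decoding for nested biomedical NER"
author: "nestNER authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured span representations and constraint-guided decoding for nested biomedical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestNER)
```

## The problem

Immunology literature is dense with nested and overlapping entity mentions:
*CD4+ T cell* (a cell phrase) contains *T cell* (a cell type); *IL-6* can
name a cytokine or its gene depending on context. Token-level tagging
schemes such as BIOES assign one tag per token and therefore cannot express
a mention inside another mention. nestNER instead treats every contiguous
token interval up to a maximum width as a candidate *span*, classifies each
span into a typed label set (plus a NONE class), and then selects a globally
consistent subset of spans under structural and ontological constraints.

The package has two halves:

1. **A structured span encoder.** Token representations feed a multi-channel
   span aggregator; span representations interact through a structural
   attention graph and span-level self-attention; a softmax classifier
   produces per-span type distributions.
2. **A constraint-guided global decoder.** Pruned high-confidence candidates
   are refined by graph message passing and ontology-aware sibling
   filtering, and the final mention set is chosen by maximizing a global
   objective that rewards confident, type-coherent spans and penalizes
   crossing spans and inadmissible label co-occurrences — exactly solvable
   by subset enumeration on small instances, approximated by beam search on
   larger ones.

## Model

### Span scoring

For a document of $T$ tokens the candidate set is every span $(s, t)$ with
$1 \le s \le t \le T$ and $t - s + 1 \le L_{max}$ (1-based inclusive token
indices; $L_{max} = 5$ by default, matching the longest template mentions
the synthetic generator emits). Token encodings $h_t \in \mathbb{R}^d$ come
from a pluggable backend; the packaged **tiny backend** is a seeded, hashed
token embedding plus positional embedding followed by a 2-layer, 2-head
self-attention stack, small enough to train from scratch on a laptop. An
adapter contract (`backend = "pretrained"`) accepts any external subword
encoder by first-subword pooling; no silent fallback exists between
backends.

A learned token similarity $\sigma(h_i^\top W h_j)$ builds a thresholded
token graph whose attention-weighted neighborhoods augment each token
(`graphAugmentTokens`) before span aggregation. Each span is then
represented by five concatenated channels — start token, end token,
elementwise mean, elementwise max, and a learned span-length embedding
$\psi_{s,t} = W_{len}[\ell] + b_{len}$ — passed through a sigmoid gate
$g = \sigma(W_g r + b_g)$, $r^{final} = g \odot r$. A 4-channel variant
without $\psi$ is available as an ablation (`use_length_embed = FALSE`).

Structural context comes from two mechanisms applied in a fixed order
(token graph → aggregation → gating → structural attention → span
self-attention → classification): masked attention over a span graph whose
edges are nesting, overlap, and adjacency relations, and full span
self-attention with a learned bias table $\phi(i, j)$ over bucketed start
distance ($0, 1, 2, 3\!-\!4, 5\!-\!8, 9+$) and nesting-depth difference
clipped to $[-2, 2]$. Span depth is *candidate-relative* — the number of
enumerated spans strictly containing the span — because no gold tree is
available at inference. Both stages use residual connections and layer
normalisation. Classification is a softmax over the labels plus NONE.

### Training objectives

Training minimizes a weighted sum of:

* **Span cross-entropy** over all enumerated spans (gold label or NONE).
  Non-entity spans vastly outnumber entities, so NONE spans are
  down-weighted by the positive-to-negative span ratio.
* **Refined-propagation cross-entropy** (weight `loss_weight_refine`,
  default 1): candidates passing a 0.5 entity-ness threshold are propagated
  over their overlap graph with the decoder's trainable mixing matrices
  ($z^{(k+1)} = \sigma(A z^{(k)} W + \tilde r U)$) and the refined
  distributions are scored against gold. This term is what trains $W$ and
  $U$; without it, decode-time message passing would run on random
  matrices and actively destroy predictions — an effect we observed and
  document as the motivation for this term.
* **Center loss** (weight $\beta$, `loss_weight_center`): squared distance
  of each predicted entity span's representation to its predicted-type
  centroid, computed per batch. Because this is a *sum* over spans of
  squared distances in a $\sim$100-dimensional normalized space, its raw
  magnitude is two to three orders larger than the cross-entropy; the
  default $\beta = 0.001$ (and $\beta = 0.01$ in the small regularizer
  study) brings it to a comparable scale. Centroids are treated as
  constants for the gradient, the standard center-loss formulation.
* **Margin contrastive loss** (off by default): hinge on the margin between
  squared distances to the own-type versus competing-type centroids.

The optimizer is decoupled-weight-decay Adam (learning rate $3 \times
10^{-5}$, weight decay 0.01, batch size 16 by default, global-norm gradient
clipping at 1), trained up to 30 epochs with early stopping after 5 epochs
without validation-F1 improvement, on a stratified 70/10/20 document split.
The $3 \times 10^{-5}$ default is a fine-tuning rate appropriate for a
large pretrained encoder; the from-scratch tiny backend uses $5 \times
10^{-3}$, a standard Adam-regime rate for small randomly initialised
networks, in all desk-scale studies below. Validation F1 during training
uses fast argmax-threshold predictions rather than full decoding, keeping
the early-stopping signal cheap; when the refine term is active these
predictions are taken from the propagation-refined distributions, so that
model selection tracks the quantity full decoding actually consumes (with
the raw-classifier metric, early stopping fires before the propagation
head has converged). Final evaluation always uses the full decoder.

### Constraint-guided decoding

Pruning keeps spans whose entity-ness $1 - P(\text{NONE})$ reaches 0.5,
capped at the top 40. The decoder then:

1. **Propagates** ($K = 2$ rounds) over a span graph connecting overlapping
   candidates and pairs whose learned similarity exceeds $\epsilon = 0.7$.
   The similarity matrix receives no gradient (edges are thresholded), so
   with an untrained checkpoint the graph reduces to overlap edges — the
   same graph the refine loss trains against.
2. **Filters** labels whose *sibling* (same parent in the type hierarchy)
   has probability $\ge \gamma = 0.5$ for the same span; labels without
   siblings are never filtered. Candidates losing all labels are dropped.
3. **Selects** the subset of (candidate, label) atoms maximizing
   $$\sum margin(s,t,y) \;-\; \lambda_1 C_{overlap} \;-\; \lambda_2
   C_{conflict} \;+\; \lambda_3 K_{context} \;+\; R_{nest},$$
   with $margin = \log \tilde P(y) - \log \tilde P(\text{NONE})$. The
   literal sum of log-probabilities is available behind
   `margin_mode = "literal"`, but since $\log P \le 0$ it makes the empty
   selection optimal whenever $\lambda_3 = 0$; the NONE-margin form
   preserves the intended ranking while making confident spans attractive,
   and is the default.

$C_{overlap}$ counts intersecting distinct span pairs, *exempting* nested
pairs licensed by the schema's nesting prior (an inner type allowed inside
an outer type) — penalizing exactly the crossing and unlicensed
configurations while leaving legitimate nesting free; a strict mode counts
every intersecting pair. $C_{conflict}$ counts structurally related pairs
(nested, overlapping, or abutting) whose labels are not admissible
together. $K_{context} = \sum_y \eta_y \log(1 + \sum e^{\alpha_{s,t}})$
rewards type-homogeneous co-occurrence, with $\alpha$ the entity-ness
score. $R_{nest}$ adds the schema nesting prior for same-type nested pairs.
Unordered pairs are counted once; defaults $\lambda_1 = \lambda_2 = 1$,
$\lambda_3 = 0.1$ are package choices (no reference values exist).

Selection is exact subset enumeration up to 16 atoms (vectorized over all
bitmasks) and beam search beyond: atoms ordered by margin, include/exclude
decisions, states scored by the partial objective plus the optimistic sum
of remaining positive margins, infeasible states (two labels on one span)
pruned immediately, `beam_width = 16` states kept. With beam width $\ge
2^n$ the beam provably sweeps the whole space and the test suite checks it
reproduces the exhaustive optimizer exactly; tie-breaks (fewer spans, then
lexicographic $(s,t,y)$) are shared by both paths so results are
deterministic.

## The type schema

A `TypeSchema` carries the label inventory, a single-parent subclass
hierarchy, the admissible co-occurrence pair set $C$, a nesting prior
$\gamma_{y,y'}$ and a frequency prior $\eta_y$, loaded from a small JSON
dialect (`loadSchema`). Design choices worth noting:

* `isAncestor` is strict (irreflexive), but the ontology projection matrix
  $\Omega$ carries 1 on the diagonal: a strictly-upper-triangular matrix
  would project every root type's score to zero, so the diagonal is the
  minimal augmentation that preserves each type's own mass.
* *Siblings* are same-parent types only (root types share a virtual root);
  mutual exclusivity across branches is expressed through the admissible
  pair set instead, keeping the sibling notion computable from the
  hierarchy alone.
* Same-label pairs are always admissible; a missing or empty
  `admissible_pairs` key means a saturated $C$ (neutral default).
* Missing priors default neutrally: $\eta_y = 1$, $\gamma_{y,y'} = 0$.
* The ontology projection $softmax(\Omega \cdot adapted(\tilde r))$ is
  computed and exposed (`ontologyProject`) but enters selection with
  weight 0: no formulation of how it should re-enter the objective is
  well-determined, so it remains diagnostic.

## The synthetic corpus generator

`generateCorpus` emulates the properties of immunology abstracts that the
method targets, without any external download:

* variable-length template mentions (1–5 tokens) for four concrete types —
  immune cells, cytokines, diseases, genes — under an abstract root, with a
  T-cell subtype nested inside cell phrases;
* gold nesting: cell templates containing a T-cell sub-phrase emit it as a
  gold inner mention with probability `nest_rate`;
* ambiguous surface forms (e.g. *TNF* as gene or cytokine) resolved by a
  deterministic cue token placed immediately after the mention, so the
  disambiguation is learnable from local context with Bayes accuracy near
  1;
* label noise (`corruptLabels`): seeded sibling flips and mention drops as
  a weak-supervision stand-in;
* per-document mention counts are $Binomial(L, \text{mention\_rate}/10)$,
  making realized counts testable against a closed-form expectation.

Gold mentions never cross: crossing spans are linguistically anomalous and
appear in this package only as injected decoder test fixtures. Generation
is byte-deterministic given (config, seed).

What passing tests on this generator do **not** show: robustness to real
tokenization noise, discontinuous mentions, long-range disambiguation, or
realistic type imbalance. The generator's templates make span
classification nearly separable; the learning study therefore validates
the training and decoding machinery, not state-of-the-art accuracy on real
corpora.

## Study conditions and problem sizes

The package's acceptance studies (reproduced by
`scripts/acceptance.R`) use the following desk-scale conditions, chosen
once and documented here:

* **Learning study**: 500 generated training documents (sentence length
  15–30, mention rate 1.5 per 10 tokens, `nest_rate` 0.3, ambiguity 0.2),
  100 held-out documents from an independent seed; tiny backend with
  $d = 32$, length embedding 16, dropout 0.1; learning rate $5 \times
  10^{-3}$, up to 30 epochs with patience 5 on a 90/10 train/validation
  split. Success is exact-match span F1 $\ge 0.80$ on the held-out set
  under full constraint decoding.
* **Decoder oracle study**: 500 random candidate sets with at most 10
  atoms (full-width beam must equal the exhaustive optimizer exactly) and
  200 with at most 12 atoms (beam width 16 must reach 99.9% of the
  optimum and match it on at least 95%).
* **Constraint efficacy study**: 10 seeds × 30 decoder-only documents,
  each with two confident gold candidates and one crossing distractor of
  moderate confidence; constraint decoding at $\lambda_1 = 10$ must never
  output a crossing pair and must match or beat the argmax-threshold
  baseline's precision on at least 8 seeds.
* **Regularizer study**: 10 seeds × 40 documents, 4 epochs, $d = 16$, no
  span-interaction layers; training with $\beta = 0.01$ must yield mean
  intra-class centroid distance (measured over gold mention
  representations, which stays well-defined even for undertrained models)
  no larger than the $\beta = 0$ run on at least 8 seeds.

## Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-12}$ before logs; softmax rows with
  no admitted entry (masked attention over an empty neighborhood) return
  zero vectors, realizing the "isolated node passes through" rule.
* Layer normalisation uses $\epsilon = 10^{-5}$.
* Gate entries are strictly inside $(0,1)$ by construction (finite
  sigmoid).
* $K = 0$ propagation is a literal identity (the input distribution object
  is returned bit-unchanged).
* Ties in pruning break by span order; ties in selection break to fewer
  spans, then the lexicographically smallest $(s, t, y)$ sequence.
* Empty documents decode to empty mention sets; empty candidate sets score
  objective 0.
* Checkpoints serialize every tensor with 17 significant digits, which
  round-trips IEEE doubles exactly; loading against a schema whose
  fingerprint differs from the one saved is an error, never a coercion.

## Known limitations

* The tiny backend is a learning-dynamics testbed, not a biomedical
  language model; F1 numbers on the synthetic corpus say nothing about
  NCBI-Disease-scale performance.
* Discontinuous mentions are rejected at the BRAT reader and unsupported
  throughout.
* The decoder's similarity matrix $W_{sim}$ receives no training signal
  (edge formation is thresholded); similarity edges therefore matter only
  with an externally trained checkpoint.
* Beam search is exact only in the full-width limit; at width 16 the test
  suite bounds its suboptimality on small instances, but no guarantee
  exists for hundreds of atoms.
* Cross-document consistency and entity normalization are out of scope.
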