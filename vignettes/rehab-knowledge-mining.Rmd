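---
title: "Mining rehabilitation knowledge from Q&A text: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining rehabilitation knowledge from Q&A text: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabminer)
```

This vignette documents the science behind `rehabminer`: the relation
model and its assumptions, what the synthetic-corpus generator does and
does not emulate, the numerical and design choices that were genuinely
open, and the package's known limitations. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The task

A record in an online rehabilitation Q&A community consists of a
question title, question content and one or more doctor answers.
Symptoms (SYM) typically appear in the question; the disease (DIS) and
rehabilitation measures (TRE) appear in the answers. Given entity
mentions, the task is to classify the relation of a (DIS, SYM) or
(DIS, TRE) pair into:

* **DS** — the symptom is a symptom of the disease;
* **SFD** — the measure is suitable for the disease;
* **NSFD** — the measure is not suitable for the disease;
* **UKN** — no relation is expressed.

Question and answers are concatenated into one text (a single-space
separator by default), because neither part alone exposes all three
entity types. Records whose mentions cover fewer than two entity types
are filtered out. The pair is annotated in place: the first entity's
span is replaced by `#`, the second by `*`, and the instance is
serialized as `label@entity1$entity2$text`. Position markers let the
classifier condition on *where* the entities sit, which matters when a
surface form occurs more than once.

Parsing splits on the first `@` and the first two `$` only, so entity
surfaces and text may contain those characters later on. Texts that
already contain a literal `#` or `*` are rejected by default; with
`escape = TRUE` the literals are escaped (`\#`, `\*`) and only the
unescaped markers count toward the exactly-one-each invariant. The `NSF`
spelling variant is accepted on read and normalised to `NSFD`.

## Stratified splitting

Instances are shuffled and split 6:2:2 into training/validation/test
with per-class stratification. Per class, the training share is
round-half-up of 0.6·n; the leftover is divided as evenly as possible
between validation and test. When a class leaves an odd instance there
is no unbiased place for it, so the package assigns it to whichever of
validation/test currently holds fewer instances (tie toward validation),
processing classes in input order. This balancing rule keeps the two
held-out sets the same size overall — with class counts 901/3602/497/235
it yields exactly 3141/1047/1047 — whereas always favouring one side
would drift by one instance per odd class. Classes with fewer than three
instances cannot populate three sets and go wholly to training, with a
warning.

## Encoder

The encoder contract is an `L × D` real matrix plus a padding mask
(`TRUE` = real token), with padding rows exactly zero. Two backends:

* **lookup** (default, self-contained): a trainable token-embedding
  table over the training vocabulary, `N(0, 0.1²)`-initialised from the
  seed, with a reserved `<unk>` row for unseen tokens. Used by every
  test and experiment in the package; `D = 32` is the working default.
* **pretrained**: an adapter slot (`embed_fn`) for an external
  contextual encoder producing, e.g., `D = 768` per-character vectors.
  The adapter is optional and treated as frozen features; no external
  weights ship with the package and none are required.

Tokenization is whitespace-based for the synthetic corpora and
per-character for unsegmented scripts; the markers `#` and `*` are
always single tokens in either mode. Sequences longer than `L` are
truncated at the head with a warning; if truncation would drop a marker
the instance is flagged invalid and excluded from training. No
normalisation is applied beyond what the input already carries.

## BiGRU + attention classifier

Standard GRU recurrences run left-to-right and right-to-left over the
unmasked positions; masked steps carry the hidden state through and emit
zero rows. The per-position outputs are concatenated into
`H ∈ R^(L×2u)` (`u = 32` per direction by default, so 64 columns).
Attention pooling computes `M = tanh(H)`, scores each position with a
trainable vector `ω`, masks padding additively with −10⁹ before the
softmax (a numerically safe stand-in for −∞), and forms
`c = Σ_t α_t H_t`. The weights are a probability simplex over real
tokens, so `c` is a convex combination of token states — the mechanism
can concentrate on the relation-bearing clause and ignore filler. A
dense softmax layer maps `c` to the four class probabilities; argmax
ties break toward the lowest label index.

Training choices that the architecture description leaves open, fixed
here as package defaults:

* **Loss and optimiser**: categorical cross-entropy with Adam at the
  configured learning rate (5e-4). Plain mini-batch SGD is available via
  `optimizer = "sgd"` for those who read "mini-batch gradient descent"
  literally; Adam is the de-facto default for this architecture family.
* **Dropout placement**: rate 0.2 on `H` (post-BiGRU, pre-attention),
  training only.
* **Checkpoint selection**: the epoch with the best validation weighted
  F1 is returned — the conservative reading of "validation is for
  tuning".
* **Class imbalance**: no loss re-weighting; imbalance is handled only
  by stratified splitting.
* **Embeddings**: the lookup table is trained jointly by default
  (`train_embeddings = FALSE` freezes it).

The backward pass is hand-derived backpropagation through time; the test
suite checks every parameter block against central-difference numeric
gradients, and checks the pooling layer against an explicit-loop oracle.

At prediction time all ordered (DIS, SYM) and (DIS, TRE) mention pairs
of a record are enumerated and classified; UKN predictions survive to
the triple list and are dropped at dictionary assembly, so downstream
consumers can still audit them.

## Evaluation

Per class, one-vs-rest precision, recall and F1 (0/0 defined as 0, so a
never-predicted class scores 0 rather than propagating NaN). The `Total`
row is the support-weighted mean of per-class values — the only common
scheme under which aggregate P, R and F1 can all differ, as they do in
practice on imbalanced data; the micro average (which collapses to
accuracy for single-label tasks) is attached as an attribute. ROC AUC
uses the rank (Mann–Whitney) statistic with average ranks on ties; PR
area uses the step-function (average-precision) rule over distinct score
thresholds, avoiding the optimism of trapezoidal interpolation. A class
absent from the truth labels has no defined curve and is reported as
missing rather than imputed.

## Knowledge dictionaries and graphs

Triples are grouped by relation into three dictionaries mapping disease
→ insertion-ordered unique value phrases. Matching is exact surface
match by default; a case-folding/whitespace-squashing mode exists
because community text is inconsistently cased. Conservation holds by
construction: kept pairs + dropped UKN + dropped duplicates equals the
input triple count. Per-disease star graphs (disease centred, one edge
per value, relation kind as edge attribute) export to GraphML and DOT.
Because answers come from many doctors, a measure can appear in both the
SFD and NSFD lists of one disease; `detect_contradictions()` reports the
exact-match (optionally case-folded) intersection with both provenance
lists, rather than silently resolving it.

## Clustering

Documents are a disease's concatenated value phrases. By default each
whole phrase is one term — values are short curated phrases, and
splitting them would conflate "hot compress" with "cold compress" — with
a word-token mode as a flag. TF-IDF uses raw counts and smoothed idf
`ln((1+N)/(1+df)) + 1`, L2-normalised, down-weighting phrases common to
every disease. PCA (mean-centred, no scaling) keeps the smallest number
of components explaining ≥ 95% variance, capped at `min(50, n − 1)`;
zero-variance input falls back to the identity with a warning.

kmeans++ seeding samples successive centers with probability
proportional to squared distance from the nearest chosen center (the
standard D² rule — probabilistic, fully seeded, rather than
deterministic farthest-point). Lloyd iterations run to a 1e-6 inertia
tolerance or 300 iterations; inertia is asserted non-increasing at every
step, and an emptied cluster is re-seeded at the point farthest from its
center. Each k runs 5 independent restarts: the lowest-inertia run is
kept and the silhouette is reported as the mean over restarts (the
alternative best-of-5 reading is available as the `silhouette_best`
field). Silhouette uses `s = (b − a)/max(a, b)` with singleton-cluster
points scored 0, the widely used convention.

Fixed defaults of k = 15 (DS), 20 (SFD), 6 (NSFD) reflect the operating
points typical for dictionaries of a few hundred diseases; a k-grid scan
maximising mean silhouette is available, with the caveat — visible in
the test fixtures — that silhouette tends to grow with k on sparse
phrase vectors as clusters shrink toward duplicates, so grids should be
capped. The report marks the largest cluster as "residual" when its
mean silhouette is negative; such a catch-all is an emergent property of
sparse TF-IDF geometry, not something the algorithm engineers.

## The synthetic corpus generator

No corpus of this kind is publicly redistributable, so the generator
plants recoverable structure in a language-neutral token alphabet
(`disN`/`symN`/`treN` entities, `wN` filler): the question embeds a
symptom, the answer names a disease and — for measure relations — a
measure next to a cue word drawn from a label-specific lexicon
(suitable: "recommended", "suitable", "take", "apply"; unsuitable:
"avoid", "reduce", "forbid", "unsuitable"; DS: diagnostic cues). UKN
records put both entities in the question and give a non-committal,
cue-free answer. Defaults were chosen once as the study conditions: the
class mix is the documented 901:3602:497:235 imbalance; noise sentences
(cue-free filler inserted before/after the relation clause) default to
rate 0.3, a realistic level of chatty filler, with 0.8 as the high-noise
setting; 30% of answers append a pronoun-style follow-up ("it needs
care") rather than repeating the disease. Generation is a pure function
of the seed.

What the generator does **not** emulate: real lexical diversity
(cue lexicons are small and disjoint, so a bag-of-cues baseline is
near-perfect on noiseless configs — the planted upper bound the test
suite checks), genuine coreference ambiguity, entity-boundary noise,
misspellings, or any specific natural language. Passing tests therefore
demonstrate that the pipeline's machinery — marking, encoding,
optimisation, pooling, bookkeeping — recovers plantable structure; they
do not certify performance on clinical text.

## Problem sizes used in tests and the acceptance script

Experiments run at a scaled operating point chosen for single-CPU
reproducibility: corpora of 800 records (300 for the noise-degradation
property), token budget `L = 64`, lookup embeddings `D = 32`, with the
full default hyperparameters (u = 32, batch 16, 40 epochs). The
architecture-contract checks run at the published dimensions `L = 200`,
`D = 768`. The attention-vs-mean-pooling comparison uses five seeds at
noise rate 0.8. Oracle-equivalence checks use hand instances of at most
ten elements at tolerance 1e-8 (1e-6 for iterative stages).

## Known limitations

* Entity mentions are assumed given; there is no named-entity
  recogniser, spelling correction or scraping.
* The pretrained-encoder adapter is frozen-features only; fine-tuning an
  external encoder is out of scope.
* Baseline architectures (SVM, CNN, plain BiGRU variants) are not
  implemented; the mean-pooling ablation is the only built-in
  comparison.
* Absolute metrics on private clinical corpora are not reproducible
  here; the package's claims are about mechanism, contracts and planted
  recovery.
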