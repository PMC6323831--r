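---
title: "Ontology ancestor channels for biomedical relation extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology ancestor channels for biomedical relation extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ontorel)
```

# The problem and the model

Given a sentence in which two biomedical entities (typically drugs) are
mentioned, the task is to decide whether the text describes a relation
between them — for drug–drug interactions (DDIs), additionally which of
four types (`mechanism`, `effect`, `advice`, `int`). Every unordered
pair of co-mentioned entities is a candidate: a sentence with E entities
yields choose(E, 2) instances.

The classifier is a multi-channel recurrent network. Each enabled
channel embeds a symbol sequence, runs it through an LSTM, and max-pools
the hidden states over time; the pooled channel vectors are
concatenated, passed through a dense layer with sigmoid activation, and
a softmax produces class probabilities. Two channel families exist:

* **Lexical channels** describe the sentence. The shortest dependency
  path (SDP) between the two entity head tokens is extracted from a
  dependency parse; every token on the path that belongs to *any*
  entity mention (candidate or bystander) is replaced by one shared
  mask string, so mention identity cannot leak through surface forms.
  The `words` channel embeds the masked path under pre-trained word2vec
  vectors (frozen by default); the `wordnet` channel embeds one coarse
  supersense class per path token (41 classes: 26 noun, 15 verb, plus a
  null class for masked or untaggable tokens).

* **Ontology channels** describe the entities. After fuzzy-linking each
  mention to a concept of an is-a DAG, the pair (c1, c2) is encoded as
  the concatenation of the two ancestor sequences
  (`concat_ancestors`) and as their common ancestors
  (`common_ancestors`). Concatenation retains each entity's full
  ancestry even when the two barely overlap; the common-ancestor
  sequence captures exactly the shared information, the same quantity
  semantic-similarity measures build on. These sequences inject curated
  domain knowledge that the sentence itself never states.

## Ancestor sequences, precisely

With T the transitive closure of the is-a edge set, Anc(c) is the set
of ancestors of c. The package returns sequences, not sets, so an
ordering convention is required; ontologies do not define one beyond
"more general first". The convention here: ascending longest-path depth
from a root (roots have depth 0), ties broken lexicographically by
concept id, and the concept itself appended in the final position. This
is deterministic, places general concepts first, and guarantees that a
proper ancestor always precedes its descendant (an ancestor's
longest-path depth is strictly smaller).

`common_ancestors(g, c1, c2)` intersects ancestors-or-self of both
concepts: for unrelated concepts this is the set of shared proper
ancestors; when one concept subsumes the other it is included itself;
and CA(c, c) equals Anc(c) with c in final position. The operation is
symmetric by construction. `concat_ancestors` is the plain
concatenation, each block ending in its own concept, with length
|Anc(c1)| + |Anc(c2)|.

## Entity linking

Mentions are linked by case-insensitive normalized Levenshtein
similarity, `1 - d/max(nchar)`, which maps edit distance onto [0, 1] so
a single threshold applies across mention lengths. The best match
against preferred labels is accepted at score ≥ 0.7; otherwise the best
synonym match is accepted only if it strictly beats the label score and
itself reaches the threshold — labels are preferred because they are the
most specific, curated nomenclature. Ties at equal score resolve to the
lowest concept id, making linking a pure function of its inputs.
Obsolete terms never match and never appear in ancestor sequences.

## Negative filtering

Candidate pairs are heavily imbalanced toward negatives. Three rules
auto-negative pairs before training: (1) both mentions have the same
text regardless of case (a drug does not interact with itself); (2)
only punctuation and whitespace separate the mentions (lists,
enumerations, abbreviation introductions) — conjunction words such as
"and" are deliberately *not* treated as punctuation; (3) both mentions'
syntactic governors are on an anti-positive list: head lemmas that
govern entities at least `min_count` times in training (default 3, a
floor against noise on small corpora) and never govern an entity of a
positive pair. Rule 3 requires *both* governors to qualify, reading the
rule literally. Auto-negatived pairs are excluded from training and
predicted negative without a network call; their gold label is kept so
that a filtered-out true interaction still scores as a miss. Filtering
partitions the pair set — nothing is dropped silently.

# Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `link threshold` | 0.7 | normalized-Levenshtein acceptance score |
| `word_dim` | from vector file | pre-trained; frozen by default |
| `wordnet_dim` | 50 | supersense embedding, trained |
| `ontology_dim` | 50 | concept embedding, trained; 50 outperformed 100/150 in the motivating experiments |
| `lstm_units` | 100 | per channel |
| `dense_units` | 100 | penultimate sigmoid layer |
| `dropout_rate` | 0.5 | embedding and pooled layers only, never the penultimate dense or output |
| `learning_rate` | 0.001 | Adam |
| `batch_size` | 64 | |
| `patience` | 3 | epochs without validation improvement; literal one-epoch stopping is noise-sensitive |
| `max_epochs` | 50 | hard cap |
| `n_classes` | 5 | or 2 for a detection-only model |

Detection results can come from either a dedicated 2-class model or
from collapsing the 5-class model's non-negative predictions; both
modes are provided and the collapsed route is the default in the
experiment driver, so detection and classification stay consistent on
one set of weights.

# Numerical and implementation choices

* The LSTM is the standard gated recurrence (input/forget/output gates,
  tanh candidate), implemented batch-vectorized on BLAS matrix
  products. Forget-gate biases initialize to 1; other weights use
  Glorot-uniform; the output layer initializes near zero so the
  untrained network is close to the uniform distribution (initial
  cross-entropy ≈ log n_classes, which the tests assert).
* Padding is index 0 and maps to a zero embedding column. Sequences are
  right-padded; masked timesteps carry the previous hidden state, so
  max-pooling over time is invariant to extra padding (asserted in the
  tests). An empty channel sequence (e.g. an unlinked entity) pools to
  the zero vector.
* Over-long sequences at inference truncate from the *left* (general)
  end, keeping the entities / self-concepts that end each block.
  Per-channel maximum lengths are fixed at training time to the longest
  observed training sequence.
* Out-of-vocabulary words share one randomly initialized unknown
  vector; unknown ontology concepts at inference are an error rather
  than silently mapped, because concept vocabulary should be built from
  the full ontology.
* Early stopping requires the validation loss to improve by more than
  1e-6; the best-epoch weights are restored. All shuffling, dropout and
  initialization derive from one user-visible seed, so training is
  reproducible to the bit on one platform.
* Models persist as a directory of text files (JSON config, TSV
  vocabularies, plain-text matrices at 17 significant digits), so a
  save/load round trip reproduces predictions exactly.
* Entity-to-token alignment uses the token containing the mention's
  last character (head-final heuristic) — deterministic and robust to
  tokenizer drift. Discontinuous mentions reduce to their first span so
  the SDP stays well-defined. The mask string defaults to a single
  shared token, `"entity"`.
* Dependency parsing is a pluggable interface (any function from
  sentence text to a single-rooted head tree). The bundled
  implementation is a deterministic chain parser; an adapter over an
  external statistical parser can be supplied by the user. The
  supersense tagger is likewise an interface, with a fixed-lexicon
  tagger and a null tagger bundled.

# The synthetic generator

`gen_synthetic_dataset()` emulates the three external inputs so every
stage is testable offline: a random rooted DAG ontology written as OBO
(a tree skeleton of bounded depth, default 4, over 40 concepts; a
second, strictly shallower parent for ~20% of non-root concepts so
multi-parent ancestry is exercised; unique pseudo-word labels and 0–2
synonyms), a DDI-dialect XML corpus, and random unit word vectors in
textual word2vec format. Generation is a pure function of the spec —
identical specs yield byte-identical files.

The corpus plants its signal in the ontology: a marker concept (depth ≥
1, subtree closest to half the concepts, so both the subtree and its
complement stay populated for sampling) defines the label rule — a pair
is positive iff the marker is a common ancestor of the two linked
concepts. Each of the 2–4 entities per sentence (probabilities
.5/.3/.2) is drawn from the marker subtree with probability
sqrt(positive_rate), so pairs are positive at the target rate (default
0.25). Surfaces are labels or synonyms, corrupted with probability 0.2
by one substitution or deletion to exercise the 0.7 linking threshold.
Filler text comes from a template vocabulary kept disjoint from all
labels and synonyms, so lexical channels can never learn the label.
Sentences group ten per document, alternating drugbank-style and
medline-style ids so the per-subset scorer has two strata. An
alternative label rule keyed to the first entity's own ancestry
(exercising the concatenation channel alone) is available behind the
`label_rule` flag.

What the generator does *not* emulate: real biomedical language (filler
text is meaningless), genuinely informative word vectors, parser errors
(the chain parse is exact), the extreme class imbalance of real DDI
corpora (≈1:5.9 positives to negatives; available via `positive_rate`
but not the default), or annotation noise. Passing the planted-signal
test therefore certifies the machinery — linking, ancestor encoding,
training — not performance on real corpora.

The planted-signal experiment (`planted_signal_experiment()`) trains on
the first 500 sentences and scores detection on the held-out 200, at
five seeds, for the ontology-channel and the words-only configurations;
the experiment caps training at 25 epochs, by which point the
validation loss on this separable task has plateaued. The anti-positive
governor list is left empty in this experiment: on template filler
text every frequent governor also governs positive-pair entities, so
the learned list is degenerate; rules 1–2 remain active.

# Known limitations

* Only is-a edges are used; part-of and other relation semantics are
  out of scope, as are information-content-weighted ancestor selection
  and semantic-similarity channels.
* The bundled chain parser is a stand-in for linguistic structure: on
  real text the SDP quality, and thus the lexical channels, depend on
  supplying a real parser through the interface.
* Ancestor counts and linking behavior on real ontologies depend on
  the ontology release; sequences are cached to TSV precisely so runs
  can pin a release.
* The pure-R network is sized for desk-scale corpora (thousands of
  instances); it is not a GPU training path.
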