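---
title: "Methods: character-aware BiLSTM-CRF tagging for biomedical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: character-aware BiLSTM-CRF tagging for biomedical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioner)
```

## The problem and the model

Biomedical NER locates and types mention spans — genes, chemicals,
diseases, species, cell lines — in scientific text. Models trained on a
single gold corpus inherit that corpus's annotation conventions and text
genre; applied "in the wild" they degrade badly. This package implements
the architecture family that addresses both issues: contextual
character-level language-model embeddings feeding a BiLSTM-CRF sequence
labeler, with one model per entity type trained on the union of all
available corpora for that type.

**Character-level language model.** A single-layer LSTM over characters,
trained by next-character cross-entropy with truncated backpropagation
through time (hidden state carried, detached, across consecutive chunks of
the stream). Two models are trained, one on the text and one on the
reversed text. Token embeddings are extracted at token boundaries: the
forward model's hidden state after the token's last character and the
backward model's hidden state after — in reversed reading order — the
token's first character. Both halves therefore summarize unbounded context
on each side of the token. Extraction processes the sentence as one
character sequence with single-space separators and touches no randomness.

**Word embeddings.** A lookup table with a subword fallback: an
out-of-vocabulary word maps to the mean of hash-bucket vectors of the
character n-grams (default n ∈ [3, 4]) of the angle-bracket-padded word.
Buckets are assigned by a 32-bit FNV-1a hash over UTF-8 bytes. This keeps
the defining behavior of fastText-style embeddings — total OOV coverage and
shared subword structure — without multi-gigabyte pretrained tables.
Lowercasing is off by default because gene symbols are case-sensitive.

**BiLSTM-CRF.** The frozen embedding stack feeds a bidirectional LSTM
(hidden size $h$ per direction); a linear projection yields per-token
emission scores $e_{t,y}$, and a transition matrix $T$ (with reserved START
and STOP states) completes a linear-chain CRF:
$$s(y) = T_{\text{START},y_1} + \sum_t e_{t,y_t} + \sum_t T_{y_t,y_{t+1}}
        + T_{y_n,\text{STOP}}.$$
Training minimizes the exact negative log-likelihood
$\log Z - s(y^\ast)$, where $\log Z$ is computed by the forward recursion in
log space with the max-shift log-sum-exp; gradients are exact expected
counts from the forward–backward marginals. Decoding is Viterbi.

## Tagging scheme and offset conventions

All offsets are 0-based half-open; `substr(text, start + 1, end)` always
reproduces a span's text. The internal tagging scheme is BIOES (the richer
boundary signal helps small models commit to span ends); IOB2 is supported
for file I/O. Decoding is lenient: any contiguous same-type non-O run forms
a span, so malformed runs (an orphan `I`/`E`, a `B` closed by `O`) are
repaired deterministically rather than dropped, and every repair or
boundary expansion is recorded in a `"warnings"` attribute. Gold mentions
whose character span does not align with token boundaries are expanded
outward to the smallest covering token run — lossless for evaluation
against character-offset gold, since evaluation compares characters, not
tokens. Overlapping gold mentions of one type are rejected at load;
overlaps across types are legal because models are per-type.

## Training procedure

Plain SGD (gradients averaged over `batch_size` sentences, global-norm
clipped) with decay-on-plateau: after `patience` epochs without dev
micro-F1 improvement the learning rate is multiplied by `lr_decay_factor`
(default 0.5); training stops at the epoch limit or when the rate falls
below `min_lr`. The returned model is the best-dev checkpoint. Batch order
is shuffled from the run seed; runs are bit-reproducible given the seed.
Char-LM and word embeddings are frozen during NER training (the embedding
matrices are inputs, not parameters), which keeps desk-scale training fast
and stable.

Key defaults, chosen for the desk scale this package targets (tens to
hundreds of sentences, embedding dims 16–64): `learning_rate = 1`
(per-sentence mean NLL of a small CRF tolerates large steps; values around
2 are routinely used in the tests), `batch_size = 8`, `patience = 3`,
`epochs = 40`. Every such choice is surfaced in `train_config()` because no
canonical setting exists at this scale.

`train_per_type()` merges corpora for one entity type: train and dev splits
are concatenated (a corpus lacking a dev split donates a seeded 10% slice
of its train split), while test splits are deliberately never merged — they
remain per source corpus so evaluation can detect corpus-specific failure.
`pretrain_finetune()` trains on a merged pool, then continues on the
target's train+dev; since dev is consumed for training in phase 2, model
selection there uses a seeded 10% holdout of the target train split. A
leakage guard rejects a pool containing the target, and each training log
carries an audit of the split labels presented to the optimizer.

## Evaluation protocols

Two mention-level protocols, both requiring type equality:

- `exact_tolerant`: each boundary independently within `tolerance`
  characters (default 1). The one-character reading absorbs differences in
  the handling of special characters around mention edges. The alternative
  interpretation — both boundaries shifted by the same offset — is stricter
  and available behind `whole_span_shift = TRUE`; the per-boundary default
  subsumes it.
- `overlap`: any shared character counts.

Matching is greedy one-to-one in `(gold.start, pred.start)` order; a
maximum bipartite matching mode exists for sensitivity checks (on small
random cases the two agree, and greedy can never exceed maximum — both are
property-tested). Precision, recall and F1 use the 0-when-undefined
convention; micro pools counts over types, macro averages per-type F1
unweighted. Matching under `exact_tolerant(t)` implies matching under any
larger tolerance, and — whenever mentions are longer than `2t` characters —
under `overlap` as well, so overlap-protocol F1 dominates exact-protocol F1
on any fixed prediction set: the monotone direction the lenient protocol is
known for, and an acceptance property of this package. (The caveat is
real: at tolerance ≥ half the mention length a tolerant match can pair
spans that share no character, e.g. gold `[5,7)` vs predicted `[7,9)` at
tolerance 2, so the domination is only asserted at the default one-character
tolerance against the multi-character mentions this domain has.)

## What the synthetic generator emulates — and what it does not

`generate_corpus()` renders sentences from templates with typed slots
filled from type-disjoint invented dictionaries (gene-symbol-like codes,
drug-like syllabic chemicals, binomial species, etc.). It emulates the
features the toolkit must be robust to:

- *Annotation-convention divergence*: `include_trailing_keyword` controls
  whether gold spans swallow a trailing type keyword ("KDR4 gene" vs
  "KDR4"), mirroring how real corpora disagree on entity boundaries;
  `boundary_jitter` moves gold ends one character inside the token
  (annotators excluding a plural "s"), exercising both the token-expansion
  policy and the one-character evaluation tolerance.
- *Surface noise*: `char_noise_rate` corrupts characters of non-entity
  words only, so gold offsets always reproduce mention text exactly.
- *Raw LM text*: periodic (known zero-entropy source), first-order Markov
  (known transition matrix, so cross-entropy lower bounds are computable),
  and template text that embeds the entity dictionaries.

All randomness flows from one seed through a named stream per split, so
splits are independently reproducible. The generator does **not** emulate
real PubMed token distributions, discourse structure, nested or
discontinuous mentions, or genre shift between abstracts and full text. A
green learnability test therefore establishes that the architecture,
gradients and decoding are correct and that the pipeline can represent and
recover span structure — not that any fixed F1 would transfer to real
corpora, which requires language-model pretraining at a scale (tens of
millions of abstracts) explicitly out of scope here.

Two conditions of the stated world deserve emphasis. First, at strong
convention divergence (half of all mentions keyworded, the default) the two
conventions contradict each other on identical contexts, so *no* single
model can be within a few points of both single-corpus models
simultaneously; merged training still strictly improves cross-convention
F1, which is the claim that matters. The "merging costs little in-corpus"
regime holds when divergence is mild (~15% of mentions), and that is where
the corresponding test operates. Second, a *half-trained* character LM can
produce worse downstream taggers than a randomly initialized one (its
features are large-scale but not yet linguistically organized); LM training
to convergence on the toy text (≈5 epochs) restores the expected ordering.

## Numerical choices

- Forward recursion and NLL in log space with max-shift log-sum-exp;
  partition agreement with exhaustive enumeration to 1e-8 on instances up
  to 6 tokens × 5 tags (acceptance property).
- Viterbi ties broken toward the lowest tag index at the latest differing
  position (the backpointer recursion takes the first maximum), so an
  all-zero score matrix decodes to all-"O" and tests are stable.
- Transitions into structurally impossible BIOES bigrams are learned by
  default (standard practice); `mask_impossible = TRUE` adds a finite −1e4
  penalty instead of −Inf so all parameters stay finite.
- LSTM gate order (input, forget, cell, output) with forget bias +1;
  parameters initialized uniform(−0.1, 0.1) from the model seed.
- Character vocabulary reserves UNK/BOS/EOS; unseen characters map to UNK
  and never error.
- Degenerate inputs: empty sentences embed to 0-row matrices and predict
  empty mention lists; empty text segments to zero sentences; an empty
  corpus pool after held-out removal is allowed with a warning.

## Known limitations

Single-layer recurrent encoders only; no transformer option. No entity
normalization or nesting within a type. Training is single-threaded
by design (deterministic, desk-scale); the package is not a route to
state-of-the-art absolute F1 without externally pretrained inputs.
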