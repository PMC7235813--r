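---
title: "Multi-level representation fusion for clinical NER: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level representation fusion for clinical NER: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlner)
```

## The task and the model

Clinical named-entity recognition over electronic medical records is framed
here as character-level BIO sequence labeling: an input sentence is a
character sequence $C = (c_1, \dots, c_n)$, and each character receives one
of 13 labels — `B-t` / `I-t` for each of six entity types (disease `Dis`,
symptom `Sym`, test `Test`, treatment `Tre`, medicine `Med`, abnormal
inspection result `Abn`) plus `O`. An entity prediction counts as correct
only under strict matching: its type and its exact character boundaries must
both equal a gold annotation.

A transformer encoder maps the sentence to a stack of hidden states
$h_1, \dots, h_L$ (one $(n \times d)$ matrix per transform-block;
$h_l = \mathrm{Trm}(h_{l-1})$, with $h_0$ the input embedding — the sum of
token, segment and position lookups). The standard tagging head uses only
$h_L$. The model this package is built around instead fuses *all* layers,
on the premise that intermediate layers carry complementary (more surface /
more syntactic) information:

* per token, the query is the projected final state, $Q = w_Q h_L + b_Q$;
* keys and values are projected per-layer states, $K_l = w_K h_l + b_K$,
  $V_l = w_V h_l + b_V$, for every layer $l$ in a configurable subset;
* each of $H$ heads attends over the *layer axis*:
  $\mathrm{head}_i = \mathrm{softmax}(Q K^\top / \sqrt{d_{head}})\, V$;
* head outputs are concatenated back to width $d$ and mixed:
  $E = \mathrm{Concat}(\mathrm{head}_1, \dots, \mathrm{head}_H)\, w_h + b_h$;
* tags come from a softmax head, $\hat Y = \mathrm{softmax}(w_O E + b_O)$.

Three comparison strategies share the same interface: feature-axis
**concatenation** of the selected layers followed by a linear projection back
to $d$; the per-layer **sum-average**; and the **last layer** alone.

### Interpreting the fused attention

Writing the fusion input as a concatenation of the $L$ layer states leaves
the softmax's item axis ambiguous — an attention over *what*? This package
commits to the reading that makes the operation well-typed and distinct from
the concatenation baseline:
**per-token attention over layers**. For each token independently, the $L$
(or $|S|$, for a subset $S$) layer vectors are the items; the query comes
from the final layer, which is therefore always part of the subset. The
alternative reading — attention over sequence positions of a concatenated
representation — would collapse into ordinary self-attention and make the
concatenation baseline redundant, so it is implemented nowhere.

Two further conventions follow standard multi-head practice, since no
alternative is specified: the $d$-wide projections are split into $H$
contiguous blocks of $d_{head} = d / H$, and the scaled dot-product divides
by $\sqrt{d_{head}}$ (the dimension of the key vectors actually dotted).
Layer-subset shorthands resolve as "the last $k$ layers": `last4` on a
12-layer encoder is layers 9–12.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `n_layers` (L) | 12 (desk scale: 4) | encoder depth = number of fused states |
| `hidden_size` (d) | 768 (desk: 64) | width of every hidden state |
| `n_encoder_heads` | 12 (desk: 4) | self-attention heads inside each block |
| `n_fusion_heads` | 12 (desk: 4) | heads of the layer-fusion attention |
| `max_sentence_length` | 64 | truncation bound; spans crossing it are dropped |
| `dropout_rate` | 0.3 | applied in training to attention/FFN outputs and the fused embedding |
| `epochs`, `batch_size` | 10, 32 | training schedule |
| `learning_rate` | 1e-5 (desk: 1e-3) | AdamW step size |
| `weight_decay` | 0.01 | decoupled decay on weight matrices only |

The package-level defaults mirror BERT-base-style fine-tuning settings
(12 layers / 768 / 12 heads, 10 epochs, batch 32, learning rate 1e-5,
dropout 0.3, maximum length 64). The *desk-scale* configs
(`encoder_config_desk()`, `train_config_desk()`) are what the tests,
experiments and reproduction script actually run: a 4-layer, 64-wide encoder
trained **from random initialization** — there is no pretraining stage in
this package — for which a fine-tuning learning rate of 1e-5 is far too
small to move the model in a few epochs. 1e-3 is the conventional Adam rate
for training small transformers from scratch and is fixed once, as a design
choice, with 5 epochs.

Other numerical choices, recorded here because the design was open:

* transform-blocks are post-layer-norm with a ReLU feed-forward of width
  $4d$ (the original encoder recipe); layer-norm $\varepsilon = 10^{-5}$;
* all weights initialize Gaussian(0, 0.02), biases 0, layer-norm gains 1;
  position embeddings are learned;
* inputs are single-segment (the tagging task has no sentence pairs), so the
  segment embedding is one shared learned vector; no special boundary tokens
  are inserted — every position is a taggable character;
* batches pad to the longest sentence in the batch; padded positions are
  masked out of attention, loss and metrics;
* tag argmax breaks ties by taking the first (lowest-index) label —
  deterministic, though ties are measure-zero in practice;
* the checkpoint returned by `train()` is the epoch with the best validation
  micro-F1 (strictly-greater comparison, so the earliest best epoch wins).

## The synthetic corpus: what it does and does not show

No annotated clinical corpus can ship with this package, so
`generate_corpus()` builds a synthetic stand-in: template-based
character sentences in which entity surface forms come from six pairwise
disjoint per-type lexicons and context characters from a disjoint context
alphabet. The default spec gives each type one private "begin" character and
three private continuation characters, which makes the character-to-tag
mapping unambiguous — the task is *separable by construction*, and a
correctly implemented model should approach strict F1 of 1.0 on held-out
data. Sentences are i.i.d.; there is no document or department structure.

That is deliberate, and it bounds what a passing test means. Green
end-to-end tests demonstrate that the machinery — corpus plumbing, encoding,
layer fusion, optimization, decoding, scoring — works and is learnable
end to end. They say nothing about performance on authentic clinical text,
where entity identity is contextual, lexicons overlap, annotation is noisy
and class balance is skewed. Likewise, rankings between assembling methods
on this corpus are not evidence about their ranking on real data: on a
separable task every method saturates. The experiment harnesses reproduce
the *design* of the published comparisons (identical splits and seeds across
cells, three repeats with the median-F1 run reported), not their outcomes.

Generator defaults: 60/20/20 splits (largest-remainder rounding, ties
resolved train → validation → test), at most 3 entities per sentence,
sentence lengths of 4–9 template slots (roughly 4–16 characters), uniform
sampling of templates, types and lexicon entries. The entity-character
fraction implied by the templates (about a third of all characters) is
property-tested against generated corpora.

## Evaluation

`evaluate()` scores strict span-level P/R/F1 per type and micro-averaged
(micro is the headline number; the macro average is also printed but marked
as such). Predicted tag sequences are decoded with the `start-new` repair
policy — an orphan `I-t` opens a new entity — matching common scorer
behavior; a `strict` mode that raises on invalid sequences is available for
debugging. Undefined ratios (zero denominators) are reported as 0, never
NaN, so micro-averages stay well-defined on degenerate inputs. Duplicate
gold spans can each be matched at most once. `evaluate_bruteforce()`
recomputes the same contract by exhaustive pairwise matching and serves as
an in-repo oracle; the test suite checks equivalence on over a thousand
randomized cases. Formula conventions are the standard ones:
$P = TP/(TP+FP)$, $R = TP/(TP+FN)$, $F1 = 2PR/(P+R)$.

## Problem sizes used in the shipped runs

The test suite and `scripts/acceptance.R` train the desk-scale encoder on a
3000-sentence corpus split 2000/500/500 (batch 32, 5 epochs), which runs in
a few minutes on one CPU and reaches validation micro-F1 1.0 by epoch 2–3;
the harness unit tests use 60–600 sentences with a 2-layer, 16–32-wide
encoder and 1–2 epochs. The pre-training loss on any corpus checks out at
$\log 13 \approx 2.565$ per token (uniform prediction over 13 tags), a
useful canary for initialization and masking bugs. Training is exactly
reproducible: two runs with one seed produce bit-identical histories and
parameters on the same platform and BLAS.

## Known limitations

* No CRF or other structured decoding — tags are predicted independently
  per token, as in the softmax-head formulation; the repair policy handles
  the (rare) invalid sequences at decode time.
* Nested or overlapping entities cannot be represented in a single BIO
  layer and are rejected by the span validator.
* The pretrained-weights adapter (`load_pretrained_adapter()`) validates and
  wraps externally supplied parameter sets with the same shapes; no
  converter from any specific public checkpoint format is bundled.
* Single CPU, dense base-R matrix math: fine for desk-scale encoders,
  not intended for 12×768 models on real corpora.
* `learning_rate` and the other desk-scale settings were chosen for
  from-scratch training on the synthetic corpus; fine-tuning real pretrained
  weights would call for the package-level defaults instead.

## A worked example

```{r example, eval = FALSE}
corpus <- generate_corpus(default_corpus_spec(n_sentences = 3000, seed = 7))
splits <- split_corpus(corpus, seed = 1)
model <- train(splits$train, splits$validation,
               encoder_config_desk(),
               aggregator_config("multihead", n_fusion_heads = 4),
               train_config_desk(seed = 11))
report <- evaluate(splits$test, predict_tags(model, splits$test))
print(report)
```
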