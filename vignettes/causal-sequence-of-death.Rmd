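---
title: "Generating causal sequences of death with encoder-decoder models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating causal sequences of death with encoder-decoder models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortseq)
```

## The problem

A death certificate records an ordered *causal sequence of death*: the
underlying cause (the disease or injury that initiated the chain of events)
followed by intermediate and immediate causes, all as ICD-10 codes. Writing
this chain correctly is a specialist task; hospital discharge records, by
contrast, are abundant and carry up to 45 priority-ordered diagnosis codes
(historically ICD-9) for the final admission. `mortseq` treats the mapping
from discharge diagnoses to the cause-of-death chain as a machine
translation problem: the diagnosis sequence is the source sentence, the
cause-of-death chain is the target sentence, and an encoder-decoder network
with attention is trained on parallel pairs.

Throughout the package the underlying cause of death is the **first** token
of the target sequence. Death certificates conventionally print the
underlying cause last (Part I is read bottom-up); we store chains
underlying-first because every metric and the constrained decoder reason
forward along cause → effect links.

## Model family

Three architectures share one stepwise decoding contract (`ms_encode()` /
`ms_step()`: a next-token log-probability vector plus an attention-weight
vector per step):

* **LSTM encoder - LSTM decoder**, optionally with *soft* (additive)
  attention, `score(s, h_i) = va' tanh(Wa s_prev + Ua h_i)`, or *general*
  (bilinear) attention, `score(s, h_i) = s' Wa h_i`. Without attention the
  final encoder state is used as a fixed context at every step.
* **Bidirectional LSTM encoder - LSTM decoder** ("brnn"): per-layer
  forward/backward passes are concatenated; the decoder is initialized by a
  learned `tanh` projection of the concatenated forward-final and
  backward-first states (the bridging is not dictated by the architecture;
  this is our choice and is isolated in one place).
* **Transformer** with multi-head scaled-dot self attention,
  `softmax(QK'/sqrt(d_k))V`, post-layer-norm residual blocks and sinusoidal
  positional encodings. The attention matrix reported to analysis code is
  the head-averaged encoder-decoder attention of the final decoder layer,
  chosen because downstream thresholding needs a single output-by-input
  matrix.

The `"full"` preset instantiates the full-scale published sizes (2x500
LSTM; BRNN layers of 500 and 250 units; a 6-layer, 8-head transformer with
2,048 feed-forward units). The `"desk"` preset (2 layers, 64 hidden units,
2 heads, 2,000 training steps, batch 32) is the default everywhere in this
package: all shipped experiments, tests and examples run on a single CPU,
so problem sizes are chosen for that budget (5,000-record corpora,
vocabularies of 400 source / 150 target codes) rather than the 181,137
decedents and 7,616/2,649-token vocabularies of the restricted state
registry data the shapes emulate. Which ordering of the published "500 and
250" BRNN units maps to which layer is not stated anywhere we could verify;
we follow list order.

Training is teacher-forced cross-entropy (the sequence log-likelihood
factorized over steps) with Adam, global gradient-norm clipping at 5, and a
fixed learning rate (default 5e-3 at desk scale; the transformer adds a
linear warmup over the first 10% of steps). Embedding size equals the
hidden size. Minibatches are drawn as random windows over the length-sorted
corpus, which keeps within-batch padding small; padded positions are masked
out of recurrent state updates, attention softmaxes and the loss. All
arithmetic is double-precision base R on a small reverse-mode autodiff
tape written for this package (an environment-per-node design with fused
LSTM-cell, attention-score and multi-head-attention operations; every
fused backward pass is verified against finite differences in the test
suite), so a fixed seed reproduces training bit for bit.

## Knowledge-constrained decoding

An ACME-style decision table lists medically valid cause → effect pairs,
either directly (`F2 F3`) or as code ranges (`F1 F2 F3`: every code in the
interval `F1..F2` may cause `F3`). Ranges expand lexicographically over the
supplied code universe — the expansion ordering is not defined by the table
format itself; lexicographic order matches how ICD-10 blocks nest. The
expanded edges form a directed knowledge graph.

Beam search keeps the top *k* hypotheses per step (default k = 5, a
conventional size; configurable). With the constraint on, a hypothesis
whose last code is `y` may only be extended with `allowed_successors(y)` or
the end-of-sequence token; candidates are filtered *before* top-k
truncation, so only feasible codes ever occupy the beam. Three decisions
the constraint semantics leave open, and how we resolved them:

* the **first** code is unconstrained (the graph encodes pairwise
  succession only, not which codes may be underlying causes);
* **end-of-sequence is always admissible** — a chain may stop at any code,
  and about 31% of real chains are a single code;
* when a code has **no feasible successor**, `constraint_fallback`
  chooses between `force_end` (default; guarantees that every adjacent
  pair of every emitted sequence is a graph edge) and
  `unconstrained_step` (a soft fallback that keeps decoding).

Hypothesis scores are raw cumulative log-probabilities; length
normalization exists but defaults to off, matching a "highest overall
probability" selection rule. Ties are broken by token index so decoding is
deterministic.

The *validity check* applies the same graph at the corpus level: a
training or validation pair is dropped iff its target chain has length at
least 2 and some **adjacent** pair is not an edge. Adjacency (rather than
all ordered pairs) is the right reading because the chain's causal claims
are exactly its neighboring links. Single-code targets bypass the filter,
and test data is never filtered. The filter is idempotent.

## The modified BLEU metric

Cause chains average 2.25 codes, so the conventional 4-gram BLEU is
meaningless here; the package uses a 2-gram variant with clipped modified
precisions `p_1`, `p_2`, **harmonic weights** `w_i = 1/i`, and the brevity
penalty `BP = 1` if `c > r`, else `exp(1 - r/c)`:

```
BLEU = BP * exp(sum_i (1/i) * log p_i) = BP * p1 * sqrt(p2)   (N = 2)
```

The harmonic weights matter: the canonical worked example (candidate
`R909 J189 J969` vs reference `R909 J189 J960`, `p1 = 2/3`, `p2 = 1/2`)
scores 0.47 = (2/3)·(1/2)^(1/2), which uniform 1/N weights cannot produce
(they give 0.577). Any zero precision gives score 0 — no smoothing, so the
published zero-score example stays exactly zero.

Single-code pairs are undefined under a 2-gram metric; rather than zeroing
roughly a third of all scores, the effective order is `min(N, c, r)`, so
such pairs are scored on 1-gram precision and BP alone and flagged
`degenerate` in the result. Corpus BLEU is the unweighted mean of
sentence-level scores (not pooled counts). Three accuracies complete the
report: exact entire-sequence match; order-free individual-code accuracy
(multiset intersection divided by the reference length — a recall-style
denominator, macro-averaged; the published definition does not pin this
down, so it is isolated in one function); and first-code (underlying
cause) accuracy.

```{r bleu-example}
bleu(c("R909", "J189", "J969"), c("R909", "J189", "J960"))
```

## Attention-based identification of death-related conditions

For a decoded record, `extract_attention()` force-decodes the generated
chain and stacks the per-step attention vectors into an output-by-input
matrix. An input diagnosis code is flagged *death-related* iff its maximum
attention over output rows reaches a threshold (default 0.1, inclusive).
Max (rather than mean or any-row) is the weakest aggregation that makes
"any strong link ⇒ related" true; the choice is ours and is recorded here
because published descriptions of this procedure show only the matrix and
the final partition.

## The synthetic world

Real multiple-cause mortality files are restricted, so the package ships a
generator whose defaults reproduce the published shape statistics of such
data: mean 18.84 diagnosis codes per decedent (Poisson, clipped to 1-45),
mean 2.25 cause codes with 31.77% single-code chains (the multi-code chain
length is 1 + Poisson(lambda) with a floor of 2, lambda calibrated
numerically so the unconditional mean is exact), and desk-scale
vocabularies of 400/150 codes (a `"full"` scale preset mirrors
7,616/2,649). A planted Erdos-Renyi causal graph (density 0.05, no self
loops, minimum out-degree 1) supplies the chains: each chain is a random
walk along edges. Each target code carries 3-8 characteristic source
codes; a record's diagnoses are the evidence codes of its chain (in chain
order, emulating priority-ordered discharge codes) followed by noise
codes. This makes the translation task learnable by construction and gives
attention a ground truth: tests verify that trained models separate
evidence from noise columns.

With `invalid_pair_plant_rate > 0`, a corresponding fraction of multi-code
chains has one adjacent pair rewired to a non-edge and the row flagged in a
ledger, so the validity filter can be tested for *exact* set equality, not
just rates.

What the generator does **not** emulate: real ICD code semantics and
comorbidity structure, demographic covariates, temporal history, coding
noise in the source sequence, and the heavy-tailed label imbalance of real
registries. Passing the synthetic recovery tests therefore demonstrates
that the pipeline is implemented correctly and can learn a planted
source-target association — not that it attains any particular accuracy on
real vital statistics data.

## Numerical and degenerate-input choices

* Decoders never emit `<pad>`, `<s>` or `<unk>`; argmax ties break toward
  the lowest vocabulary index; beam ties break by token-index order.
* Attention softmaxes use additive masks of -1e30 on padded positions; a
  fully masked row yields a zero (guarded) distribution rather than NaN.
* Log-probabilities are normalized to logsumexp 0 within 1e-5; attention
  rows sum to 1 within 1e-5 (exact up to double rounding).
* Empty generations are scored 0 on every metric via an out-of-vocabulary
  placeholder.
* LSTM forget-gate biases initialize to 1; other recurrent weights are
  uniform(-0.08, 0.08); transformer weights are Xavier-uniform.

## Known limitations

* Absolute scores on restricted registry data are out of reach by design;
  the acceptance surface is the worked metric examples, oracle
  equivalences and behavioral guarantees on the synthetic corpus.
* The constrained decoder guarantees feasibility, not accuracy; on the
  synthetic corpus (as in the published experience) constraining an
  already well-trained model mostly cannot help and may hurt.
* Training is single-threaded R; desk-scale models train in minutes, but
  the full-scale presets are provided for architecture fidelity (and are
  shape-tested), not for routine training in R.
* Masked-language-model pretraining is out of scope: with ~2-code targets
  and ~31% single-code targets, masking the only token of a target leaves
  nothing to recover from.
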