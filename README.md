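# mortseq

Neural generation of **causal sequences of death** — the ordered ICD-10
cause-of-death codes on a death certificate, underlying cause first — from
the diagnosis codes of a decedent's last hospitalization.

The package is aimed at mortality-coding and epidemiological-modelling
work: it frames death-certificate chain construction as sequence-to-sequence
translation (diagnosis codes → cause-of-death codes) and provides, in pure R:

* **Encoder-decoder models** — LSTM, bidirectional-LSTM and transformer —
  with soft (additive) attention `va' tanh(Wa s + Ua h_i)`, general
  (bilinear) attention `s' Wa h_i`, and multi-head scaled-dot self-attention
  `softmax(QK'/√d_k)V`, trained by teacher-forced cross-entropy on a small
  reverse-mode autodiff engine built into the package.
* **Knowledge-constrained beam search**: an ACME-style decision table of
  medically valid cause→effect pairs becomes a directed graph, and each
  next code can be restricted to feasible successors of the previous one.
* **Validity-check preprocessing**: training/validation pairs whose target
  chains contain an invalid adjacent pair are removed (test data never is).
* **A modified BLEU metric** for short chains: clipped 1-/2-gram precisions,
  harmonic weights `w_i = 1/i`, brevity penalty `BP = 1 (c > r)` or
  `exp(1 − r/c) (c ≤ r)`, so `BLEU = BP · p₁ · √p₂`; plus entire-sequence,
  order-free individual-code, and underlying-cause accuracies.
* **Attention analysis**: the output×input attention matrix of a decoded
  record, and thresholding (default 0.1) to flag death-related diagnosis
  codes.
* **A synthetic mortality-corpus generator** with a planted causal graph
  and ground-truth ledger, matching the published shape of restricted state
  vital-statistics data (mean 18.84 diagnoses, mean 2.25 causes, ~31.8%
  single-code chains), so the entire pipeline is testable without
  restricted data.

## Worked example

```r
library(mortseq)

# the metric on a worked pair of cause chains
bleu(c("R909", "J189", "J969"), c("R909", "J189", "J960"))
#> <bleu_result> score 0.4714 (x100: 47.1) | p = [0.6667, 0.5000] | BP 1.0000

# a synthetic world: planted causal graph + evidence map
w  <- generate_world(synthetic_config(seed = 11))
cp <- generate_corpus(w, 5000, seed = 12)
pairs <- records_to_pairs(cp$records)
sp <- split_dataset(pairs, seed = 13)

sv <- build_vocabulary(lapply(sp$train, `[[`, "source"))
tv <- build_vocabulary(lapply(sp$train, `[[`, "target"))
m  <- train_model(sp$train, sv, tv,
                  model_config("lstm", "general", train_steps = 2000L, seed = 14))

res <- greedy_decode(m, sp$test[[1]]$source)
res$tokens            # generated cause-of-death chain, underlying cause first
death_related_conditions(res$attention, threshold = 0.1)
```

On this 5,000-record desk-scale corpus (single CPU, ~5 minutes of
training) the run above printed:

```
<evaluation_report> n = 300
  BLEU (x100):             76.98 (sd 31.65)
  Entire sequence acc:     61.67%
  Individual codes acc:    88.55%
  Underlying COD acc:      99.67%
```

i.e. the model recovers the planted diagnosis→cause association almost
perfectly for the underlying cause and for most full chains. (Synthetic
data is deliberately easier than real registry data; see the vignette for
what these numbers do and do not show.)

Constrained decoding against the planted graph:

```r
out <- beam_search(m, sp$test[[1]]$source,
                   beam_config(k = 5, constrained = TRUE),
                   graph = w$graph)
```

With `constraint_fallback = "force_end"` every adjacent pair of every
generated chain is an edge of the knowledge graph, by construction.

## Command line

A thin wrapper over the same functions ships in `inst/cli/mortseq.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mortseq.R", package="mortseq"))')" \
    experiment --config experiment.yaml --verbose
```

Subcommands: `generate | preprocess | train | translate | evaluate |
experiment` (the last runs the full 5-fold protocol for one experiment cell
and reports mean (sd) across folds). Config is one YAML file per
experiment; see `read_experiment_config()`.

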