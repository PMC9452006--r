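# Independent oracles and tiny fixtures shared across the suite.

# ---- brute-force BLEU oracle ------------------------------------------------
# Written independently of the package implementation: explicit loops, no
# shared helpers. weights[i] is applied to log p_i.
oracle_ngram_list <- function(x, n) {
  out <- list()
  if (length(x) >= n) {
    for (s in 1:(length(x) - n + 1)) out[[length(out) + 1]] <- x[s:(s + n - 1)]
  }
  out
}

oracle_clipped_precision <- function(cand, ref, n) {
  cg <- oracle_ngram_list(cand, n)
  rg <- oracle_ngram_list(ref, n)
  if (length(cg) == 0) return(NA_real_)
  used <- rep(FALSE, length(rg))
  hits <- 0
  for (g in cg) {
    for (j in seq_along(rg)) {
      if (!used[j] && identical(rg[[j]], g)) {
        used[j] <- TRUE
        hits <- hits + 1
        break
      }
    }
  }
  hits / length(cg)
}

oracle_bleu <- function(cand, ref, weights = c(1, 1 / 2)) {
  cl <- length(cand); rl <- length(ref)
  bp <- if (cl > rl) 1 else exp(1 - rl / cl)
  n_eff <- min(length(weights), cl, rl)
  acc <- 0
  for (i in seq_len(n_eff)) {
    p <- oracle_clipped_precision(cand, ref, i)
    if (p == 0) return(0)
    acc <- acc + weights[i] * log(p)
  }
  bp * exp(acc)
}

# ---- toy Markov model implementing the stepwise contract --------------------
# Next-token log-probabilities depend only on the previous token, through a
# random (seeded) transition table. Vocabulary: 4 specials + n real codes.
toy_model <- function(n_tokens = 4, seed = 1, src_len = 3) {
  set.seed(seed)
  tokens <- c("<pad>", "<s>", "</s>", "<unk>",
              sprintf("T%02d", seq_len(n_tokens)))
  V <- length(tokens)
  logits <- matrix(rnorm(V * V, sd = 2), V, V)
  logp <- t(apply(logits, 1, function(r) r - max(r) - log(sum(exp(r - max(r))))))
  idx <- seq_len(V); names(idx) <- tokens
  vocab <- structure(list(tokens = tokens, index = idx,
                          specials = tokens[1:4],
                          pad = 1L, sos = 2L, eos = 3L, unk = 4L),
                     class = "vocabulary")
  structure(list(logp = logp, tgt_vocab = vocab, src_len = src_len,
                 config = list(max_source_len = 45L)),
            class = c("toy_model"))
}

ms_encode_toy <- function(model, source) {
  list(source = source, m = length(source))
}

ms_step_toy <- function(model, state, prev_token) {
  pid <- unname(model$tgt_vocab$index[prev_token])
  lp <- model$logp[pid, ]
  names(lp) <- model$tgt_vocab$tokens
  list(logp = lp, attn = rep(1 / state$m, state$m), state = state)
}

registerS3method("ms_encode", "toy_model", ms_encode_toy,
                 envir = asNamespace("mortseq"))
registerS3method("ms_step", "toy_model", ms_step_toy,
                 envir = asNamespace("mortseq"))

# exhaustive best-sequence search matching beam-search scoring semantics:
# sequences of real tokens with length < max_length are scored including the
# end-of-sequence step; sequences at max_length are scored without it.
oracle_exhaustive_best <- function(model, source, max_length) {
  v <- model$tgt_vocab
  real <- v$tokens[-(1:4)]
  best <- list(score = -Inf, tokens = character(0))
  score_seq <- function(toks, with_eos) {
    prev <- "<s>"
    state <- mortseq::ms_encode(model, source)
    s <- 0
    for (tk in toks) {
      st <- mortseq::ms_step(model, state, prev)
      s <- s + st$logp[[tk]]
      state <- st$state
      prev <- tk
    }
    if (with_eos) {
      st <- mortseq::ms_step(model, state, prev)
      s <- s + st$logp[["</s>"]]
    }
    s
  }
  # empty output (immediate end) is also a candidate
  sc0 <- score_seq(character(0), TRUE)
  if (sc0 > best$score) best <- list(score = sc0, tokens = character(0))
  grids <- list()
  for (L in seq_len(max_length)) {
    combos <- do.call(expand.grid,
                      c(rep(list(real), L), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(combos))) {
      toks <- as.character(unlist(combos[r, ], use.names = FALSE))
      sc <- score_seq(toks, with_eos = L < max_length)
      if (sc > best$score) best <- list(score = sc, tokens = toks)
    }
  }
  best
}

# ---- small real-model fixtures ---------------------------------------------
tiny_corpus <- function(n = 60, seed = 5, n_src = 40, n_tgt = 12) {
  w <- generate_world(synthetic_config(
    n_source_codes = n_src, n_target_codes = n_tgt,
    mean_diagnoses = 6, mean_cod_length = 2,
    single_code_target_fraction = 0.3, edge_density = 0.15, seed = seed))
  cp <- generate_corpus(w, n, seed = seed + 1)
  pairs <- records_to_pairs(cp$records)
  list(world = w, corpus = cp, pairs = pairs,
       sv = build_vocabulary(lapply(pairs, function(p) p$source)),
       tv = build_vocabulary(lapply(pairs, function(p) p$target)))
}

tiny_model <- function(fix, architecture = "lstm", attention = "general",
                       train_steps = 0L, seed = 9, ...) {
  cfg <- model_config(architecture, attention, hidden_size = 16L,
                      num_layers = 2L, brnn_layer_sizes = c(16L, 8L),
                      transformer_ff_size = 32L, num_heads = 2L,
                      train_steps = as.integer(train_steps),
                      batch_size = 16L, seed = seed, ...)
  if (train_steps > 0) train_model(fix$pairs, fix$sv, fix$tv, cfg)
  else new_model(cfg, fix$sv, fix$tv)
}

# numerical gradient of f wrt a parameter environment, central differences
numeric_grad <- function(f, param, eps = 1e-5) {
  g <- param$val * 0
  for (i in seq_along(param$val)) {
    old <- param$val[i]
    param$val[i] <- old + eps; up <- f()
    param$val[i] <- old - eps; dn <- f()
    param$val[i] <- old
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}
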