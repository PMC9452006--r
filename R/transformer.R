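# Transformer encoder-decoder (post-layer-norm variant) on the autodiff
# tape. Rows are laid out sequence-major: row (b-1)*m + t holds position t
# of batch sequence b, matching op_multihead_attn.

.sinusoidal_pos <- function(maxlen, d) {
  P <- matrix(0, maxlen, d)
  pos <- seq_len(maxlen) - 1L
  for (j in seq_len(d)) {
    k <- (j - 1L) %/% 2L
    ang <- pos / (10000^(2 * k / d))
    P[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  P
}

.causal_mask <- function(t) {
  m <- matrix(0, t, t)
  m[upper.tri(m)] <- -1e30
  m
}

# per-sequence additive key mask over padded source positions
.key_masks <- function(src_mat, pad, mq) {
  lapply(seq_len(nrow(src_mat)), function(b) {
    bad <- src_mat[b, ] == pad
    mk <- ncol(src_mat)
    mm <- matrix(0, mq, mk)
    mm[, bad] <- -1e30
    mm
  })
}

.tf_embed <- function(model, tape, ids_mat, emb_param, train) {
  d <- model$config$hidden_size
  batch <- nrow(ids_mat); m <- ncol(ids_mat)
  x <- op_rows(tape, td_leaf(tape, emb_param), as.integer(t(ids_mat)))
  x <- op_scale(tape, x, sqrt(d))
  pos <- .sinusoidal_pos(m, d)[rep(seq_len(m), batch), , drop = FALSE]
  x <- op_add(tape, x, td_const(tape, pos))
  if (isTRUE(model$config$dropout > 0) && train)
    x <- op_dropout(tape, x, model$config$dropout)
  x
}

.tf_mha_block <- function(model, tape, x_q, x_kv, prefix, batch, mq, mk, mask) {
  P <- model$params
  nh <- model$config$num_heads
  q <- op_matmul(tape, x_q, td_leaf(tape, P[[paste0(prefix, "q")]]))
  k <- op_matmul(tape, x_kv, td_leaf(tape, P[[paste0(prefix, "k")]]))
  v <- op_matmul(tape, x_kv, td_leaf(tape, P[[paste0(prefix, "v")]]))
  a <- op_multihead_attn(tape, q, k, v, batch, mq, mk, nh, mask)
  out <- op_matmul(tape, a, td_leaf(tape, P[[paste0(prefix, "o")]]))
  list(out = out, attn = a$attn)
}

.tf_ffn <- function(model, tape, x, lp) {
  P <- model$params
  h <- op_relu(tape, op_add(tape,
    op_matmul(tape, x, td_leaf(tape, P[[paste0(lp, "_ffW1")]])),
    td_leaf(tape, P[[paste0(lp, "_ffb1")]])))
  op_add(tape, op_matmul(tape, h, td_leaf(tape, P[[paste0(lp, "_ffW2")]])),
         td_leaf(tape, P[[paste0(lp, "_ffb2")]]))
}

.tf_ln <- function(model, tape, x, lp, which) {
  P <- model$params
  op_layernorm(tape, x, td_leaf(tape, P[[paste0(lp, "_ln", which, "g")]]),
               td_leaf(tape, P[[paste0(lp, "_ln", which, "b")]]))
}

.tf_encode <- function(model, tape, src_mat, train = FALSE) {
  cfg <- model$config
  batch <- nrow(src_mat); m <- ncol(src_mat)
  masks <- .key_masks(src_mat, model$src_vocab$pad, m)
  x <- .tf_embed(model, tape, src_mat, model$params$src_emb, train)
  for (l in seq_len(cfg$num_layers)) {
    lp <- paste0("enc", l)
    a <- .tf_mha_block(model, tape, x, x, paste0(lp, "_W"), batch, m, m, masks)
    x <- .tf_ln(model, tape, op_add(tape, x, a$out), lp, 1L)
    f <- .tf_ffn(model, tape, x, lp)
    x <- .tf_ln(model, tape, op_add(tape, x, f), lp, 2L)
  }
  x
}

# decoder over a teacher-forced prefix; returns logits node and the final
# layer's head-averaged cross-attention (list per sequence, T x m)
.tf_decode <- function(model, tape, din_mat, memory, src_mat, train = FALSE) {
  cfg <- model$config
  batch <- nrow(din_mat); Tm <- ncol(din_mat); m <- ncol(src_mat)
  cmask <- .causal_mask(Tm)
  xmasks <- .key_masks(src_mat, model$src_vocab$pad, Tm)
  x <- .tf_embed(model, tape, din_mat, model$params$tgt_emb, train)
  cross_attn <- NULL
  for (l in seq_len(cfg$num_layers)) {
    lp <- paste0("dec", l)
    a <- .tf_mha_block(model, tape, x, x, paste0(lp, "_sW"), batch, Tm, Tm, cmask)
    x <- .tf_ln(model, tape, op_add(tape, x, a$out), lp, 1L)
    cr <- .tf_mha_block(model, tape, x, memory, paste0(lp, "_cW"),
                        batch, Tm, m, xmasks)
    x <- .tf_ln(model, tape, op_add(tape, x, cr$out), lp, 2L)
    cross_attn <- cr$attn
    f <- .tf_ffn(model, tape, x, lp)
    x <- .tf_ln(model, tape, op_add(tape, x, f), lp, 3L)
  }
  logits <- op_add(tape, op_matmul(tape, x, td_leaf(tape, model$params$Wout)),
                   td_leaf(tape, model$params$bout))
  list(logits = logits, cross_attn = cross_attn)
}

.transformer_batch_loss <- function(model, tape, src_ids, tgt_ids) {
  v <- model$tgt_vocab
  src_mat <- .pad_ids(src_ids, model$src_vocab$pad)
  din <- lapply(tgt_ids, function(y) c(v$sos, y))
  dout <- lapply(tgt_ids, function(y) c(y, v$eos))
  din_mat <- .pad_ids(din, v$pad)
  dout_mat <- .pad_ids(dout, v$pad)
  memory <- .tf_encode(model, tape, src_mat, train = TRUE)
  dd <- .tf_decode(model, tape, din_mat, memory, src_mat, train = TRUE)
  # logits rows are sequence-major (b-1)*T + t; flatten targets to match
  targets <- as.integer(t(dout_mat))
  weights <- as.numeric(t(dout_mat) != v$pad) * 1
  op_softmax_xent(tape, dd$logits, targets, weights)
}
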