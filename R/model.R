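#' Encoder-decoder model configuration
#'
#' Three architectures share a uniform stepwise decoding contract:
#' `"lstm"` (unidirectional LSTM encoder + LSTM decoder), `"brnn"`
#' (bidirectional LSTM encoder + LSTM decoder) and `"transformer"`.
#' Attention must be `"self"` iff the architecture is the transformer;
#' `"soft"` (additive) and `"general"` (bilinear) pair with the recurrent
#' encoders, and `"none"` falls back to a fixed final-state context.
#'
#' The `"full"` preset instantiates the full-scale published
#' architectures: a 2-layer LSTM with 500 hidden units per layer, a 2-layer
#' bidirectional LSTM with 500 and 250 hidden units, and a transformer with
#' six stacked layers, 2,048 feed-forward units and eight heads. The
#' `"desk"` preset (2 layers, 64 units, 2 heads, 2,000 steps) is sized for
#' single-CPU experimentation and is the package-wide default.
#'
#' @param architecture one of `"lstm"`, `"brnn"`, `"transformer"`.
#' @param attention one of `"none"`, `"soft"`, `"general"`, `"self"`.
#' @param preset `"desk"` or `"full"`; sets size defaults which explicit
#'   arguments override.
#' @param num_layers,hidden_size,brnn_layer_sizes,transformer_ff_size,num_heads
#'   architecture sizes.
#' @param dropout dropout rate used during training.
#' @param train_steps,batch_size,learning_rate training regime.
#' @param seed integer seed controlling initialization and batch order.
#' @param max_source_len,max_target_len hard sequence-length caps (45
#'   diagnosis codes, 18 cause-of-death codes).
#' @return a `model_config` list.
#' @export
model_config <- function(architecture = c("lstm", "brnn", "transformer"),
                         attention = NULL,
                         preset = c("desk", "full"),
                         num_layers = NULL,
                         hidden_size = NULL,
                         brnn_layer_sizes = NULL,
                         transformer_ff_size = NULL,
                         num_heads = NULL,
                         dropout = 0,
                         train_steps = 2000L,
                         batch_size = 32L,
                         learning_rate = 5e-3,
                         seed = 1L,
                         max_source_len = 45L,
                         max_target_len = 18L) {
  architecture <- match.arg(architecture)
  preset <- match.arg(preset)
  if (is.null(attention))
    attention <- if (architecture == "transformer") "self" else "general"
  attention <- match.arg(attention, c("none", "soft", "general", "self"))
  if ((attention == "self") != (architecture == "transformer"))
    stop("attention 'self' is used iff architecture is 'transformer'; ",
         "'soft'/'general'/'none' pair with 'lstm'/'brnn'")
  full <- preset == "full"
  if (is.null(num_layers))
    num_layers <- if (architecture == "transformer") (if (full) 6L else 2L) else 2L
  if (is.null(hidden_size))
    hidden_size <- if (full) {
      if (architecture == "transformer") 512L else 500L
    } else 64L
  if (is.null(brnn_layer_sizes))
    brnn_layer_sizes <- if (full) c(500L, 250L) else c(64L, 32L)
  if (is.null(transformer_ff_size))
    transformer_ff_size <- if (full) 2048L else 128L
  if (is.null(num_heads)) num_heads <- if (full) 8L else 2L
  if (architecture == "transformer" && hidden_size %% num_heads != 0)
    stop("hidden_size must be divisible by num_heads")
  if (architecture == "brnn" && num_layers != length(brnn_layer_sizes))
    num_layers <- length(brnn_layer_sizes)
  structure(list(
    architecture = architecture, attention = attention, preset = preset,
    num_layers = as.integer(num_layers), hidden_size = as.integer(hidden_size),
    brnn_layer_sizes = as.integer(brnn_layer_sizes),
    transformer_ff_size = as.integer(transformer_ff_size),
    num_heads = as.integer(num_heads), dropout = dropout,
    train_steps = as.integer(train_steps), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed),
    max_source_len = as.integer(max_source_len),
    max_target_len = as.integer(max_target_len)
  ), class = "model_config")
}

.unif_init <- function(nr, nc, a = 0.08) {
  td_param(matrix(stats::runif(nr * nc, -a, a), nr, nc))
}

.xavier_init <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  td_param(matrix(stats::runif(nr * nc, -a, a), nr, nc))
}

.zeros_init <- function(nr, nc) td_param(matrix(0, nr, nc))
.ones_init <- function(nr, nc) td_param(matrix(1, nr, nc))

# LSTM weight with forget-gate bias 1 (gate order i, f, o, g)
.lstm_bias <- function(H) {
  b <- matrix(0, 1L, 4L * H)
  b[1L, H + seq_len(H)] <- 1
  td_param(b)
}

# Initialize all parameters for a config + vocabularies. Returns a named
# list of td_param environments.
.init_params <- function(config, n_src, n_tgt) {
  E <- config$hidden_size
  H <- config$hidden_size
  P <- list()
  if (config$architecture == "transformer") {
    d <- config$hidden_size
    ff <- config$transformer_ff_size
    P$src_emb <- .xavier_init(n_src, d)
    P$tgt_emb <- .xavier_init(n_tgt, d)
    for (l in seq_len(config$num_layers)) {
      for (nm in c("q", "k", "v", "o"))
        P[[paste0("enc", l, "_W", nm)]] <- .xavier_init(d, d)
      P[[paste0("enc", l, "_ln1g")]] <- .ones_init(1L, d)
      P[[paste0("enc", l, "_ln1b")]] <- .zeros_init(1L, d)
      P[[paste0("enc", l, "_ffW1")]] <- .xavier_init(d, ff)
      P[[paste0("enc", l, "_ffb1")]] <- .zeros_init(1L, ff)
      P[[paste0("enc", l, "_ffW2")]] <- .xavier_init(ff, d)
      P[[paste0("enc", l, "_ffb2")]] <- .zeros_init(1L, d)
      P[[paste0("enc", l, "_ln2g")]] <- .ones_init(1L, d)
      P[[paste0("enc", l, "_ln2b")]] <- .zeros_init(1L, d)
    }
    for (l in seq_len(config$num_layers)) {
      for (nm in c("q", "k", "v", "o"))
        P[[paste0("dec", l, "_sW", nm)]] <- .xavier_init(d, d)
      P[[paste0("dec", l, "_ln1g")]] <- .ones_init(1L, d)
      P[[paste0("dec", l, "_ln1b")]] <- .zeros_init(1L, d)
      for (nm in c("q", "k", "v", "o"))
        P[[paste0("dec", l, "_cW", nm)]] <- .xavier_init(d, d)
      P[[paste0("dec", l, "_ln2g")]] <- .ones_init(1L, d)
      P[[paste0("dec", l, "_ln2b")]] <- .zeros_init(1L, d)
      P[[paste0("dec", l, "_ffW1")]] <- .xavier_init(d, ff)
      P[[paste0("dec", l, "_ffb1")]] <- .zeros_init(1L, ff)
      P[[paste0("dec", l, "_ffW2")]] <- .xavier_init(ff, d)
      P[[paste0("dec", l, "_ffb2")]] <- .zeros_init(1L, d)
      P[[paste0("dec", l, "_ln3g")]] <- .ones_init(1L, d)
      P[[paste0("dec", l, "_ln3b")]] <- .zeros_init(1L, d)
    }
    P$Wout <- .xavier_init(d, n_tgt)
    P$bout <- .zeros_init(1L, n_tgt)
    return(P)
  }

  P$src_emb <- .unif_init(n_src, E)
  P$tgt_emb <- .unif_init(n_tgt, E)

  if (config$architecture == "lstm") {
    He <- H
    for (l in seq_len(config$num_layers)) {
      nin <- if (l == 1L) E else H
      P[[paste0("enc_W", l)]] <- .unif_init(nin + H, 4L * H)
      P[[paste0("enc_b", l)]] <- .lstm_bias(H)
    }
  } else {  # brnn
    sizes <- config$brnn_layer_sizes
    for (l in seq_along(sizes)) {
      nin <- if (l == 1L) E else 2L * sizes[l - 1L]
      s <- sizes[l]
      P[[paste0("brnn_Wf", l)]] <- .unif_init(nin + s, 4L * s)
      P[[paste0("brnn_bf", l)]] <- .lstm_bias(s)
      P[[paste0("brnn_Wb", l)]] <- .unif_init(nin + s, 4L * s)
      P[[paste0("brnn_bb", l)]] <- .lstm_bias(s)
    }
    He <- 2L * sizes[length(sizes)]
    # bridge encoder summary -> decoder initial (h, c) per decoder layer
    for (l in seq_len(config$num_layers)) {
      P[[paste0("bridge_Wh", l)]] <- .unif_init(He, H)
      P[[paste0("bridge_Wc", l)]] <- .unif_init(He, H)
    }
  }

  dec_in1 <- if (config$attention %in% c("soft", "none")) E + He else E
  for (l in seq_len(config$num_layers)) {
    nin <- if (l == 1L) dec_in1 else H
    P[[paste0("dec_W", l)]] <- .unif_init(nin + H, 4L * H)
    P[[paste0("dec_b", l)]] <- .lstm_bias(H)
  }

  if (config$attention == "general") {
    P$att_Wa <- .unif_init(H, He)
    P$att_Wc <- .unif_init(He + H, H)
  } else if (config$attention == "soft") {
    P$att_Wa <- .unif_init(H, H)
    P$att_Ua <- .unif_init(He, H)
    P$att_va <- .unif_init(H, 1L)
  }
  P$Wout <- .unif_init(H, n_tgt)
  P$bout <- .zeros_init(1L, n_tgt)
  P
}

# encoder output dimension
.enc_dim <- function(config) {
  if (config$architecture == "brnn")
    2L * config$brnn_layer_sizes[length(config$brnn_layer_sizes)]
  else config$hidden_size
}

#' Instantiate an untrained model
#'
#' Parameters are initialized deterministically from `config$seed`.
#'
#' @param config a `model_config`.
#' @param src_vocab,tgt_vocab `vocabulary` objects.
#' @return a `seq2seq_model` (classed additionally by architecture).
#' @export
new_model <- function(config, src_vocab, tgt_vocab) {
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  params <- .init_params(config, length(src_vocab$tokens), length(tgt_vocab$tokens))
  cls <- if (config$architecture == "transformer") "ms_transformer" else "ms_rnn"
  structure(list(config = config, params = params,
                 src_vocab = src_vocab, tgt_vocab = tgt_vocab),
            class = c(cls, "seq2seq_model"))
}

#' @export
print.seq2seq_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$val), numeric(1)))
  cat("<seq2seq_model> ", x$config$architecture, "/", x$config$attention,
      ", ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Named parameter shapes of a model
#'
#' @param model a `seq2seq_model`.
#' @return named list of integer `c(rows, cols)` shapes.
#' @export
model_param_shapes <- function(model) {
  lapply(model$params, function(p) dim(p$val))
}

## ---- batch preparation ----

# Pad a list of id vectors to a matrix (rows = batch) with pad_id.
.pad_ids <- function(ids_list, pad_id) {
  m <- max(lengths(ids_list))
  out <- matrix(pad_id, length(ids_list), m)
  for (b in seq_along(ids_list)) {
    v <- ids_list[[b]]
    out[b, seq_along(v)] <- v
  }
  out
}

## ---- training ----

#' Train an encoder-decoder model
#'
#' Teacher-forced cross-entropy over the parallel corpus, optimized with
#' Adam and global gradient-norm clipping for `config$train_steps`
#' minibatch steps. With a fixed seed and fixed data the loss trajectory
#' and the final parameters are reproducible bit for bit (all arithmetic is
#' double-precision base R).
#'
#' @param pairs non-empty list of `seq_pair` training pairs.
#' @param src_vocab,tgt_vocab vocabularies.
#' @param config a `model_config`.
#' @param log_every record the running loss every this many steps.
#' @return a trained `seq2seq_model`; `$log` holds a data frame of
#'   (step, loss) and `$final_loss` the last minibatch loss.
#' @export
train_model <- function(pairs, src_vocab, tgt_vocab, config,
                        log_every = 100L) {
  if (length(pairs) == 0) stop("empty training corpus")
  over <- which(vapply(pairs, function(p)
    length(p$source) > config$max_source_len ||
    length(p$target) > config$max_target_len, logical(1)))
  if (length(over) > 0)
    stop("pair(s) exceed length caps at index: ",
         paste(utils::head(over, 5), collapse = ", "))
  model <- new_model(config, src_vocab, tgt_vocab)
  restore <- .Random.seed_guard(config$seed + 1L)
  on.exit(restore(), add = TRUE)

  src_ids <- lapply(pairs, function(p) vocab_encode(src_vocab, p$source))
  tgt_ids <- lapply(pairs, function(p) vocab_encode(tgt_vocab, p$target))
  n <- length(pairs)
  # length-bucketed batching: drawing a random window over the length-sorted
  # corpus keeps within-batch padding small without biasing the sample much
  len_order <- order(lengths(src_ids), sample.int(n))
  opt <- adam_state(model$params)
  warmup <- if (config$architecture == "transformer")
    max(1L, round(0.1 * config$train_steps)) else 0L

  log_steps <- integer(0); log_loss <- numeric(0)
  loss_val <- NA_real_
  for (step in seq_len(config$train_steps)) {
    bs <- min(config$batch_size, n)
    start <- sample.int(n, 1L)
    idx <- len_order[((start + seq_len(bs) - 2L) %% n) + 1L]
    tape <- td_tape()
    attr(tape, "training") <- TRUE
    loss_node <- .batch_loss(model, tape, src_ids[idx], tgt_ids[idx])
    zero_grads(model$params)
    td_backward(tape, loss_node)
    lr <- if (warmup > 0L && step < warmup)
      config$learning_rate * step / warmup else config$learning_rate
    opt <- adam_step(opt, lr = lr)
    loss_val <- loss_node$val[1L, 1L]
    if (step %% log_every == 0L || step == config$train_steps) {
      log_steps <- c(log_steps, step); log_loss <- c(log_loss, loss_val)
    }
  }
  model$log <- data.frame(step = log_steps, loss = log_loss)
  model$final_loss <- loss_val
  model
}

# dispatch: tape loss for one minibatch
.batch_loss <- function(model, tape, src_ids, tgt_ids) {
  if (model$config$architecture == "transformer")
    .transformer_batch_loss(model, tape, src_ids, tgt_ids)
  else .rnn_batch_loss(model, tape, src_ids, tgt_ids)
}

## ---- recurrent forward (shared by training and inference) ----

# Run the (possibly bidirectional) encoder on a padded id matrix.
# Returns list(Hcat = node batch x (m*He), init = list per decoder layer of
# hc nodes batch x 2H, mask = batch x m 0/1 matrix).
.rnn_encode_batch <- function(model, tape, src_mat) {
  cfg <- model$config
  P <- model$params
  batch <- nrow(src_mat); m <- ncol(src_mat)
  pad <- model$src_vocab$pad
  mask <- (src_mat != pad) * 1
  # embedding row order: sequence-major, row (b-1)*m + t
  emb_all <- op_rows(tape, td_leaf(tape, P$src_emb), as.integer(t(src_mat)))
  if (isTRUE(cfg$dropout > 0) && isTRUE(attr(tape, "training")))
    emb_all <- op_dropout(tape, emb_all, cfg$dropout)
  x_nodes <- vector("list", m)
  for (t in seq_len(m)) {
    rows <- (seq_len(batch) - 1L) * m + t
    x_nodes[[t]] <- .op_pickrows(tape, emb_all, rows)
  }

  if (cfg$architecture == "lstm") {
    H <- cfg$hidden_size
    layer_in <- x_nodes
    final_hc <- vector("list", cfg$num_layers)
    for (l in seq_len(cfg$num_layers)) {
      W <- td_leaf(tape, P[[paste0("enc_W", l)]])
      b <- td_leaf(tape, P[[paste0("enc_b", l)]])
      hc <- td_const(tape, matrix(0, batch, 2L * H))
      outs <- vector("list", m)
      for (t in seq_len(m)) {
        hc <- op_lstm_cell(tape, layer_in[[t]], hc, W, b, mask[, t])
        outs[[t]] <- op_cols(tape, hc, seq_len(H))
      }
      final_hc[[l]] <- hc
      layer_in <- outs
    }
    Hcat <- op_cbind(tape, layer_in)
    final_top <- op_cols(tape, final_hc[[cfg$num_layers]], seq_len(H))
    list(Hcat = Hcat, init = final_hc, mask = mask, m = m, He = H,
         final_top = final_top)
  } else {
    sizes <- cfg$brnn_layer_sizes
    layer_in <- x_nodes
    fwd_last <- NULL; bwd_first <- NULL
    for (l in seq_along(sizes)) {
      s <- sizes[l]
      Wf <- td_leaf(tape, P[[paste0("brnn_Wf", l)]])
      bf <- td_leaf(tape, P[[paste0("brnn_bf", l)]])
      Wb <- td_leaf(tape, P[[paste0("brnn_Wb", l)]])
      bb <- td_leaf(tape, P[[paste0("brnn_bb", l)]])
      hcf <- td_const(tape, matrix(0, batch, 2L * s))
      fouts <- vector("list", m)
      for (t in seq_len(m)) {
        hcf <- op_lstm_cell(tape, layer_in[[t]], hcf, Wf, bf, mask[, t])
        fouts[[t]] <- op_cols(tape, hcf, seq_len(s))
      }
      hcb <- td_const(tape, matrix(0, batch, 2L * s))
      bouts <- vector("list", m)
      for (t in rev(seq_len(m))) {
        hcb <- op_lstm_cell(tape, layer_in[[t]], hcb, Wb, bb, mask[, t])
        bouts[[t]] <- op_cols(tape, hcb, seq_len(s))
      }
      layer_in <- lapply(seq_len(m), function(t)
        op_cbind(tape, list(fouts[[t]], bouts[[t]])))
      fwd_last <- op_cols(tape, hcf, seq_len(s))
      bwd_first <- op_cols(tape, hcb, seq_len(s))
    }
    He <- 2L * sizes[length(sizes)]
    summ <- op_cbind(tape, list(fwd_last, bwd_first))
    H <- cfg$hidden_size
    init <- vector("list", cfg$num_layers)
    for (l in seq_len(cfg$num_layers)) {
      h0 <- op_tanh(tape, op_matmul(tape, summ,
              td_leaf(tape, P[[paste0("bridge_Wh", l)]])))
      c0 <- op_tanh(tape, op_matmul(tape, summ,
              td_leaf(tape, P[[paste0("bridge_Wc", l)]])))
      init[[l]] <- op_cbind(tape, list(h0, c0))
    }
    Hcat <- op_cbind(tape, layer_in)
    list(Hcat = Hcat, init = init, mask = mask, m = m, He = He,
         final_top = summ)
  }
}

# pick arbitrary rows of a node (gather with scatter-add backward)
.op_pickrows <- function(tape, a, rows) {
  node <- td_node(tape, a$val[rows, , drop = FALSE])
  node$bw <- function(self) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[rows, ] <- g[rows, ] + self$grad
    .td_acc(a, g)
  }
  node
}

# One decoder step on the tape. dec is an environment carrying decoder
# loop state (hc per layer, s_top, leaves). Returns list(logits, alpha).
.rnn_decoder_step <- function(model, tape, dec, enc, prev_emb) {
  cfg <- model$config
  H <- cfg$hidden_size
  att <- cfg$attention
  amask <- (1 - enc$mask) * -1e30   # additive mask over source positions

  if (att == "soft") {
    sc <- op_soft_scores(tape, dec$s_top, enc$Hcat, dec$att_Wa, dec$att_Ua,
                         dec$att_va, enc$m)
    alpha <- op_softmax_rows(tape, sc, amask)
    ctx <- op_attn_context(tape, alpha, enc$Hcat, enc$m)
    x <- op_cbind(tape, list(prev_emb, ctx))
  } else if (att == "none") {
    ctx <- dec$fixed_ctx
    x <- op_cbind(tape, list(prev_emb, ctx))
    alpha <- NULL
  } else {  # general
    x <- prev_emb
    alpha <- NULL
  }

  for (l in seq_len(cfg$num_layers)) {
    dec$hc[[l]] <- op_lstm_cell(tape, x, dec$hc[[l]], dec$W[[l]], dec$b[[l]])
    x <- op_cols(tape, dec$hc[[l]], seq_len(H))
  }
  dec$s_top <- x

  if (att == "general") {
    sc <- op_general_scores(tape, dec$s_top, enc$Hcat, dec$att_Wa, enc$m)
    alpha <- op_softmax_rows(tape, sc, amask)
    ctx <- op_attn_context(tape, alpha, enc$Hcat, enc$m)
    htilde <- op_tanh(tape, op_matmul(tape,
      op_cbind(tape, list(ctx, dec$s_top)), dec$att_Wc))
    logits <- op_add(tape, op_matmul(tape, htilde, dec$Wout), dec$bout)
  } else {
    logits <- op_add(tape, op_matmul(tape, dec$s_top, dec$Wout), dec$bout)
  }
  list(logits = logits, alpha = alpha)
}

# set up the decoder loop environment from encoder results
.rnn_decoder_init <- function(model, tape, enc, batch) {
  cfg <- model$config
  P <- model$params
  H <- cfg$hidden_size
  dec <- new.env(parent = emptyenv())
  dec$W <- lapply(seq_len(cfg$num_layers), function(l)
    td_leaf(tape, P[[paste0("dec_W", l)]]))
  dec$b <- lapply(seq_len(cfg$num_layers), function(l)
    td_leaf(tape, P[[paste0("dec_b", l)]]))
  dec$Wout <- td_leaf(tape, P$Wout)
  dec$bout <- td_leaf(tape, P$bout)
  if (cfg$attention == "general") {
    dec$att_Wa <- td_leaf(tape, P$att_Wa)
    dec$att_Wc <- td_leaf(tape, P$att_Wc)
  } else if (cfg$attention == "soft") {
    dec$att_Wa <- td_leaf(tape, P$att_Wa)
    dec$att_Ua <- td_leaf(tape, P$att_Ua)
    dec$att_va <- td_leaf(tape, P$att_va)
  }
  dec$hc <- enc$init
  dec$s_top <- op_cols(tape, dec$hc[[cfg$num_layers]], seq_len(H))
  if (cfg$attention == "none") {
    # fixed context at every step: the encoder's summary state (final
    # mask-carried top state for the LSTM; forward-final/backward-first
    # concatenation for the BRNN) -- the classic fixed-length-vector
    # encoder-decoder
    dec$fixed_ctx <- enc$final_top
  }
  dec
}

# teacher-forced minibatch loss for recurrent architectures
.rnn_batch_loss <- function(model, tape, src_ids, tgt_ids) {
  cfg <- model$config
  v <- model$tgt_vocab
  batch <- length(src_ids)
  src_mat <- .pad_ids(src_ids, model$src_vocab$pad)
  # decoder input: <s> y1..yT ; output: y1..yT </s>
  din <- lapply(tgt_ids, function(y) c(v$sos, y))
  dout <- lapply(tgt_ids, function(y) c(y, v$eos))
  Tm <- max(lengths(din))
  din_mat <- .pad_ids(din, v$pad)
  dout_mat <- .pad_ids(dout, v$pad)
  wt <- (dout_mat != v$pad) * 1

  enc <- .rnn_encode_batch(model, tape, src_mat)
  dec <- .rnn_decoder_init(model, tape, enc, batch)
  emb_leaf <- td_leaf(tape, model$params$tgt_emb)

  logit_nodes <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    prev_emb <- op_rows(tape, emb_leaf, as.integer(din_mat[, t]))
    st <- .rnn_decoder_step(model, tape, dec, enc, prev_emb)
    logit_nodes[[t]] <- st$logits
  }
  all_logits <- .op_rbind(tape, logit_nodes)
  targets <- as.integer(dout_mat)        # column-major: step-major blocks
  weights <- as.numeric(wt)
  op_softmax_xent(tape, all_logits, targets, weights)
}

.op_rbind <- function(tape, parts) {
  hs <- vapply(parts, function(p) nrow(p$val), integer(1))
  node <- td_node(tape, do.call(rbind, lapply(parts, function(p) p$val)))
  node$bw <- function(self) {
    at <- 0L
    for (j in seq_along(parts)) {
      .td_acc(parts[[j]], self$grad[at + seq_len(hs[j]), , drop = FALSE])
      at <- at + hs[j]
    }
  }
  node
}
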