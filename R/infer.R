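#' Encode a source sequence into an initialized decoder state
#'
#' The first half of the uniform stepwise decoding contract shared by all
#' architectures (and by any object implementing these generics, e.g. toy
#' models in tests).
#'
#' @param model a `seq2seq_model`.
#' @param source character vector of source codes (normalized on entry;
#'   out-of-vocabulary codes map to `<unk>`).
#' @return an opaque decoder state for [ms_step()].
#' @export
ms_encode <- function(model, source) UseMethod("ms_encode")

#' Advance the decoder by one token
#'
#' The second half of the stepwise contract: given the state and the
#' previously emitted token (`"<s>"` to start), returns the normalized
#' log-probability vector over the target vocabulary, the attention-weight
#' vector over source positions, and the advanced state. Advancing the same
#' state twice with the same token gives identical results.
#'
#' @param model a `seq2seq_model`.
#' @param state a state from [ms_encode()] or a prior step.
#' @param prev_token the previously emitted target token.
#' @return list with `logp` (named numeric over target vocabulary), `attn`
#'   (numeric over source positions; attribute `informative = FALSE` when
#'   the architecture has no attention), and `state`.
#' @export
ms_step <- function(model, state, prev_token) UseMethod("ms_step")

.check_source <- function(model, source) {
  source <- normalize_icd(source)
  if (length(source) > model$config$max_source_len)
    stop("source sequence longer than max_source_len (",
         model$config$max_source_len, "): ", length(source))
  source
}

.log_softmax <- function(x) {
  mx <- max(x)
  x - (mx + log(sum(exp(x - mx))))
}

#' @export
ms_encode.ms_rnn <- function(model, source) {
  source <- .check_source(model, source)
  ids <- vocab_encode(model$src_vocab, source)
  tape <- td_tape()
  enc <- .rnn_encode_batch(model, tape, matrix(ids, 1L))
  cfg <- model$config
  structure(list(
    arch = "rnn",
    source = source,
    Hcat = enc$Hcat$val,
    mask = enc$mask,
    m = enc$m,
    He = enc$He,
    hc = lapply(enc$init, function(n) n$val),
    s_top = enc$init[[cfg$num_layers]]$val[, seq_len(cfg$hidden_size), drop = FALSE],
    fixed_ctx = if (cfg$attention == "none") enc$final_top$val
  ), class = "decoder_state")
}

#' @export
ms_step.ms_rnn <- function(model, state, prev_token) {
  cfg <- model$config
  P <- model$params
  v <- model$tgt_vocab
  prev_id <- vocab_encode(v, prev_token)

  tape <- td_tape()
  enc <- list(Hcat = td_const(tape, state$Hcat), mask = state$mask,
              m = state$m, He = state$He)
  dec <- new.env(parent = emptyenv())
  dec$W <- lapply(seq_len(cfg$num_layers), function(l)
    td_leaf(tape, P[[paste0("dec_W", l)]]))
  dec$b <- lapply(seq_len(cfg$num_layers), function(l)
    td_leaf(tape, P[[paste0("dec_b", l)]]))
  dec$Wout <- td_leaf(tape, P$Wout)
  dec$bout <- td_leaf(tape, P$bout)
  if (cfg$attention == "general") {
    dec$att_Wa <- td_leaf(tape, P$att_Wa); dec$att_Wc <- td_leaf(tape, P$att_Wc)
  } else if (cfg$attention == "soft") {
    dec$att_Wa <- td_leaf(tape, P$att_Wa); dec$att_Ua <- td_leaf(tape, P$att_Ua)
    dec$att_va <- td_leaf(tape, P$att_va)
  }
  dec$hc <- lapply(state$hc, function(m_) td_const(tape, m_))
  dec$s_top <- td_const(tape, state$s_top)
  if (cfg$attention == "none") dec$fixed_ctx <- td_const(tape, state$fixed_ctx)

  prev_emb <- op_rows(tape, td_leaf(tape, P$tgt_emb), prev_id)
  st <- .rnn_decoder_step(model, tape, dec, enc, prev_emb)

  logp <- .log_softmax(st$logits$val[1L, ])
  names(logp) <- v$tokens
  if (is.null(st$alpha)) {
    attn <- rep(1 / state$m, state$m)
    attr(attn, "informative") <- FALSE
  } else {
    attn <- as.numeric(st$alpha$val[1L, ])
  }
  new_state <- state
  new_state$hc <- lapply(dec$hc, function(n) n$val)
  new_state$s_top <- dec$s_top$val
  list(logp = logp, attn = attn, state = new_state)
}

#' @export
ms_encode.ms_transformer <- function(model, source) {
  source <- .check_source(model, source)
  ids <- vocab_encode(model$src_vocab, source)
  tape <- td_tape()
  src_mat <- matrix(ids, 1L)
  memory <- .tf_encode(model, tape, src_mat)
  structure(list(
    arch = "transformer",
    source = source,
    memory = memory$val,
    src_mat = src_mat,
    m = ncol(src_mat),
    prefix = integer(0)
  ), class = "decoder_state")
}

#' @export
ms_step.ms_transformer <- function(model, state, prev_token) {
  v <- model$tgt_vocab
  prev_id <- vocab_encode(v, prev_token)
  state$prefix <- c(state$prefix, prev_id)
  tape <- td_tape()
  memory <- td_const(tape, state$memory)
  dd <- .tf_decode(model, tape, matrix(state$prefix, 1L), memory, state$src_mat)
  Tm <- length(state$prefix)
  logp <- .log_softmax(dd$logits$val[Tm, ])
  names(logp) <- v$tokens
  attn <- as.numeric(dd$cross_attn[[1L]][Tm, ])
  list(logp = logp, attn = attn, state = state)
}

#' Sequence log-likelihood under a model
#'
#' Sum of stepwise log-probabilities of `target` (plus the end-of-sequence
#' token) given `source`; agrees with the teacher-forced training
#' objective.
#'
#' @param model a `seq2seq_model`.
#' @param source,target character code vectors.
#' @return scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(model, source, target) {
  v <- model$tgt_vocab
  state <- ms_encode(model, source)
  toks <- c("<s>", normalize_icd(target))
  ids <- vocab_encode(v, c(normalize_icd(target), "</s>"))
  ll <- 0
  for (t in seq_along(ids)) {
    st <- ms_step(model, state, toks[t])
    ll <- ll + st$logp[[ids[t]]]
    state <- st$state
  }
  ll
}
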