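#' Beam search configuration
#'
#' @param k beam size (>= 1); default 5.
#' @param max_length maximum generated sequence length (default 18, the
#'   cause-of-death cap).
#' @param constrained restrict each next code to medically feasible
#'   successors of the previous one (requires a knowledge graph at decode
#'   time).
#' @param constraint_fallback what to do when a hypothesis's last code has
#'   no feasible successor: `"force_end"` (default; emit end-of-sequence,
#'   guaranteeing every adjacent pair of the output is a graph edge) or
#'   `"unconstrained_step"` (fall back to an unrestricted step).
#' @param length_normalization divide hypothesis scores by their length
#'   when selecting the final output (default off: the highest overall
#'   probability path wins).
#' @return a `beam_config` list.
#' @export
beam_config <- function(k = 5L, max_length = 18L, constrained = FALSE,
                        constraint_fallback = c("force_end", "unconstrained_step"),
                        length_normalization = FALSE) {
  constraint_fallback <- match.arg(constraint_fallback)
  if (k < 1) stop("beam size k must be >= 1")
  if (max_length < 1) stop("max_length must be >= 1")
  structure(list(k = as.integer(k), max_length = as.integer(max_length),
                 constrained = constrained,
                 constraint_fallback = constraint_fallback,
                 length_normalization = length_normalization),
            class = "beam_config")
}

# indices of special tokens a decoder must never emit (pad, sos, unk)
.banned_ids <- function(vocab) c(vocab$pad, vocab$sos, vocab$unk)

#' Greedy decoding
#'
#' Emits the argmax token at each step (ties broken by lowest vocabulary
#' index), stopping at the end-of-sequence token or `max_length`.
#'
#' @param model a model implementing [ms_encode()]/[ms_step()].
#' @param source character vector of source codes.
#' @param max_length maximum output length.
#' @return list with `tokens` (generated codes, specials stripped),
#'   `attention` (one row per generated code x source positions) and
#'   `score` (cumulative log-probability including the end token when
#'   emitted).
#' @export
greedy_decode <- function(model, source, max_length = 18L) {
  v <- model$tgt_vocab
  state <- ms_encode(model, source)
  banned <- .banned_ids(v)
  prev <- "<s>"
  tokens <- character(0)
  attn <- list()
  score <- 0
  for (t in seq_len(max_length)) {
    st <- ms_step(model, state, prev)
    lp <- st$logp
    lp[banned] <- -Inf
    best <- which.max(lp)                 # first max = lowest index on ties
    score <- score + lp[[best]]
    if (best == v$eos) break
    tokens <- c(tokens, v$tokens[best])
    attn[[length(attn) + 1L]] <- st$attn
    state <- st$state
    prev <- v$tokens[best]
  }
  A <- if (length(attn) > 0) do.call(rbind, attn) else
    matrix(numeric(0), 0L, length(state$source))
  dimnames(A) <- list(tokens, state$source)
  list(tokens = tokens, attention = A, score = score)
}

#' Beam-search decoding with optional knowledge constraint
#'
#' Standard beam search over the stepwise decoder: at each step every live
#' hypothesis is extended, the top `k` candidates overall are kept, and
#' candidates ending in the end-of-sequence token move to the finished
#' pool. When `beam$constrained` is on, a hypothesis whose last emitted
#' code is `y` may only be extended with a feasible successor of `y` in the
#' knowledge graph, or end-of-sequence (always admissible; a causal chain
#' may stop at any code). The first code is unconstrained: the graph
#' encodes pairwise succession only. Candidates are filtered against the
#' graph before top-k truncation. Deterministic: score ties are broken by
#' token-index order.
#'
#' @param model a model implementing [ms_encode()]/[ms_step()].
#' @param source character vector of source codes.
#' @param beam a [beam_config()].
#' @param graph a `knowledge_graph`; required when `beam$constrained`.
#' @return list with `tokens`, `attention`, `score` (the selected
#'   hypothesis's cumulative log-probability; length-normalized score used
#'   for selection when configured).
#' @export
beam_search <- function(model, source, beam = beam_config(), graph = NULL) {
  if (isTRUE(beam$constrained) && is.null(graph))
    stop("constrained beam search requires a knowledge graph")
  v <- model$tgt_vocab
  banned <- .banned_ids(v)
  state0 <- ms_encode(model, source)

  new_hyp <- function(ids, tokens, state, score, attn)
    list(ids = ids, tokens = tokens, state = state, score = score, attn = attn)
  live <- list(new_hyp(integer(0), character(0), state0, 0, list()))
  finished <- list()

  for (step_i in seq_len(beam$max_length)) {
    cand <- list()
    for (h in live) {
      prev <- if (length(h$tokens) == 0) "<s>" else h$tokens[length(h$tokens)]
      st <- ms_step(model, h$state, prev)
      lp <- st$logp
      lp[banned] <- -Inf
      if (isTRUE(beam$constrained) && length(h$tokens) > 0) {
        succ <- allowed_successors(graph, h$tokens[length(h$tokens)])
        succ_ids <- unname(v$index[succ])
        succ_ids <- succ_ids[!is.na(succ_ids)]
        if (length(succ_ids) == 0) {
          if (beam$constraint_fallback == "force_end") {
            keep <- v$eos
            mask <- rep(-Inf, length(lp)); mask[keep] <- 0
            lp <- lp + mask
          } # unconstrained_step: leave lp as-is
        } else {
          keep <- c(succ_ids, v$eos)
          mask <- rep(-Inf, length(lp)); mask[keep] <- 0
          lp <- lp + mask
        }
      }
      ok <- which(is.finite(lp))
      if (length(ok) > beam$k) ok <- ok[order(-lp[ok])][seq_len(beam$k)]
      for (tok_id in ok) {
        cand[[length(cand) + 1L]] <- list(
          hyp = h, tok_id = tok_id, step = st, score = h$score + lp[[tok_id]])
      }
    }
    if (length(cand) == 0) break
    sc <- vapply(cand, function(cn) cn$score, numeric(1))
    key <- vapply(cand, function(cn)
      paste(sprintf("%06d", c(cn$hyp$ids, cn$tok_id)), collapse = ""),
      character(1))
    sel <- order(-sc, key)[seq_len(min(beam$k, length(cand)))]
    live <- list()
    for (ci in sel) {
      cn <- cand[[ci]]
      if (cn$tok_id == v$eos) {
        finished[[length(finished) + 1L]] <- new_hyp(
          cn$hyp$ids, cn$hyp$tokens, NULL, cn$score, cn$hyp$attn)
      } else {
        live[[length(live) + 1L]] <- new_hyp(
          c(cn$hyp$ids, cn$tok_id),
          c(cn$hyp$tokens, v$tokens[cn$tok_id]),
          cn$step$state, cn$score,
          c(cn$hyp$attn, list(cn$step$attn)))
      }
    }
    if (length(live) == 0) break
  }
  # live hypotheses at max_length count as finished without an end token
  for (h in live)
    finished[[length(finished) + 1L]] <- new_hyp(h$ids, h$tokens, NULL,
                                                 h$score, h$attn)
  stopifnot(length(finished) > 0)
  fsc <- vapply(finished, function(h) {
    if (isTRUE(beam$length_normalization)) h$score / max(length(h$tokens) + 1L, 1L)
    else h$score
  }, numeric(1))
  fkey <- vapply(finished, function(h)
    paste(sprintf("%06d", h$ids), collapse = ""), character(1))
  best <- finished[[order(-fsc, fkey)[1L]]]
  A <- if (length(best$attn) > 0) do.call(rbind, best$attn) else
    matrix(numeric(0), 0L, length(state0$source))
  dimnames(A) <- list(best$tokens, state0$source)
  list(tokens = best$tokens, attention = A, score = best$score)
}

#' Translate a list of source sequences
#'
#' @param model a `seq2seq_model`.
#' @param sources list of character vectors.
#' @param beam a [beam_config()]; `k = 1` unconstrained uses greedy
#'   decoding.
#' @param graph optional `knowledge_graph` for constrained decoding.
#' @return list of decode results (`tokens`, `attention`, `score`).
#' @export
translate_sequences <- function(model, sources, beam = beam_config(),
                                graph = NULL) {
  lapply(sources, function(s) beam_search(model, s, beam, graph))
}

#' Write translations and an optional score/attention sidecar
#'
#' One space-joined generated sequence per input line, mirroring the
#' parallel-corpus format; the sidecar TSV holds per-sequence scores and
#' row-major attention matrices.
#'
#' @param results list from [translate_sequences()].
#' @param path output file.
#' @param sidecar_path optional TSV sidecar path.
#' @export
write_translations <- function(results, path, sidecar_path = NULL) {
  writeLines(vapply(results, function(r) paste(r$tokens, collapse = " "),
                    character(1)), path)
  if (!is.null(sidecar_path)) {
    rows <- vapply(seq_along(results), function(i) {
      r <- results[[i]]
      paste(i, sprintf("%.6f", r$score),
            paste(sprintf("%.6f", as.numeric(t(r$attention))), collapse = ","),
            sep = "\t")
    }, character(1))
    writeLines(c("index\tscore\tattention_row_major", rows), sidecar_path)
  }
  invisible(path)
}
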