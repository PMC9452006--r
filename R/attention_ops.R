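#' Additive (soft) attention score
#'
#' The alignment score between the previous decoder hidden state and one
#' encoder hidden state: `va' tanh(Wa s_prev + Ua h_i)`. Softmax over all
#' source positions turns these scores into attention weights.
#'
#' @param s_prev numeric vector, previous decoder hidden state.
#' @param h_i numeric vector, encoder hidden state at source position i.
#' @param Wa,Ua,va parameter matrices (`Wa`: d x |s|, `Ua`: d x |h|, `va`:
#'   numeric vector of length d).
#' @return scalar score.
#' @export
soft_attention_score <- function(s_prev, h_i, Wa, Ua, va) {
  s_prev <- as.numeric(s_prev); h_i <- as.numeric(h_i); va <- as.numeric(va)
  if (ncol(Wa) != length(s_prev) || ncol(Ua) != length(h_i) ||
      nrow(Wa) != length(va) || nrow(Ua) != length(va))
    stop("attention parameter dimensions do not conform")
  sum(va * tanh(Wa %*% s_prev + Ua %*% h_i))
}

#' Bilinear (general) attention score
#'
#' The Luong-style alignment score `s_t' Wa h_i` between the current
#' decoder hidden state and one encoder hidden state.
#'
#' @param s_t numeric vector, current decoder hidden state.
#' @param h_i numeric vector, encoder hidden state.
#' @param Wa parameter matrix (|s| x |h|).
#' @return scalar score.
#' @export
general_attention_score <- function(s_t, h_i, Wa) {
  s_t <- as.numeric(s_t); h_i <- as.numeric(h_i)
  if (nrow(Wa) != length(s_t) || ncol(Wa) != length(h_i))
    stop("attention parameter dimensions do not conform")
  as.numeric(t(s_t) %*% Wa %*% h_i)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, the self-attention primitive of the
#' transformer. Each row of the returned weight matrix sums to 1.
#'
#' @param Q,K,V query, key and value matrices; `ncol(Q) == ncol(K)` is the
#'   key dimension d_k, and `nrow(K) == nrow(V)`.
#' @return list with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (`nrow(Q) x nrow(K)`).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  if (ncol(K) < 1) stop("key dimension must be positive")
  w <- .softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = w %*% V, weights = w)
}

#' Normalize attention scores into weights
#'
#' @param scores numeric vector of alignment scores.
#' @return numeric vector of softmax weights summing to 1.
#' @export
attention_weights <- function(scores) {
  as.numeric(.softmax_rows(matrix(scores, 1L)))
}
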