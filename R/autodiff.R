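# Reverse-mode automatic differentiation over base-R matrices.
#
# A tape records nodes in creation order; backward() walks them in reverse.
# Nodes are environments with fields: val (matrix), grad (NULL until
# backward reaches them), bw (closure adding this node's gradient into its
# parents). Trainable parameters live outside the tape as `td_param`
# environments; a fresh leaf node wraps each one per forward pass and its
# bw accumulates into param$grad.
#
# Recurrent cells and attention scoring are fused ops with hand-derived
# backward passes: one tape node per LSTM cell instead of ~15, which keeps
# the interpreter overhead negligible relative to the BLAS calls.

td_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

.td_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

td_node <- function(tape, val, bw = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$bw <- bw
  .td_push(tape, node)
}

.td_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' @keywords internal
td_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p
}

# wrap a parameter as a tape leaf
td_leaf <- function(tape, param) {
  node <- td_node(tape, param$val)
  node$bw <- function(self) {
    param$grad <- if (is.null(param$grad)) self$grad else param$grad + self$grad
  }
  node
}

td_const <- function(tape, val) td_node(tape, val)

td_backward <- function(tape, loss_node) {
  loss_node$grad <- matrix(1, nrow(loss_node$val), ncol(loss_node$val))
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$bw)) node$bw(node)
  }
  invisible(NULL)
}

## ---- generic ops ----

op_matmul <- function(tape, a, b) {
  node <- td_node(tape, a$val %*% b$val)
  node$bw <- function(self) {
    .td_acc(a, self$grad %*% t(b$val))
    .td_acc(b, crossprod(a$val, self$grad))
  }
  node
}

# a + b where b may be a 1-row bias broadcast over rows of a
op_add <- function(tape, a, b) {
  bias <- nrow(b$val) == 1L && nrow(a$val) > 1L
  v <- if (bias) sweep(a$val, 2L, b$val[1L, ], "+") else a$val + b$val
  node <- td_node(tape, v)
  node$bw <- function(self) {
    .td_acc(a, self$grad)
    .td_acc(b, if (bias) matrix(colSums(self$grad), 1L) else self$grad)
  }
  node
}

op_mul <- function(tape, a, b) {
  node <- td_node(tape, a$val * b$val)
  node$bw <- function(self) {
    .td_acc(a, self$grad * b$val)
    .td_acc(b, self$grad * a$val)
  }
  node
}

op_scale <- function(tape, a, k) {
  node <- td_node(tape, a$val * k)
  node$bw <- function(self) .td_acc(a, self$grad * k)
  node
}

op_tanh <- function(tape, a) {
  v <- tanh(a$val)
  node <- td_node(tape, v)
  node$bw <- function(self) .td_acc(a, self$grad * (1 - v * v))
  node
}

op_relu <- function(tape, a) {
  v <- pmax(a$val, 0)
  node <- td_node(tape, v)
  node$bw <- function(self) .td_acc(a, self$grad * (a$val > 0))
  node
}

op_cols <- function(tape, a, idx) {
  node <- td_node(tape, a$val[, idx, drop = FALSE])
  node$bw <- function(self) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[, idx] <- self$grad
    .td_acc(a, g)
  }
  node
}

op_cbind <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  node <- td_node(tape, do.call(cbind, lapply(parts, function(p) p$val)))
  node$bw <- function(self) {
    at <- 0L
    for (j in seq_along(parts)) {
      .td_acc(parts[[j]], self$grad[, at + seq_len(widths[j]), drop = FALSE])
      at <- at + widths[j]
    }
  }
  node
}

# embedding lookup: rows of a parameter matrix, with scatter-add backward
op_rows <- function(tape, a, idx) {
  node <- td_node(tape, a$val[idx, , drop = FALSE])
  node$bw <- function(self) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    for (r in seq_along(idx)) g[idx[r], ] <- g[idx[r], ] + self$grad[r, ]
    .td_acc(a, g)
  }
  node
}

# dropout as a fixed Bernoulli mask drawn at op creation (inverted scaling)
op_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1L, 1 - rate) / (1 - rate),
                 nrow(a$val), ncol(a$val))
  node <- td_node(tape, a$val * mask)
  node$bw <- function(self) .td_acc(a, self$grad * mask)
  node
}

# row-wise softmax with an optional additive mask (-Inf at disallowed cells)
op_softmax_rows <- function(tape, a, add_mask = NULL) {
  v <- .softmax_rows(a$val, add_mask)
  node <- td_node(tape, v)
  node$bw <- function(self) {
    .td_acc(a, (self$grad - rowSums(self$grad * v)) * v)
  }
  node
}

.softmax_rows <- function(x, add_mask = NULL) {
  if (!is.null(add_mask)) x <- x + add_mask
  mx <- apply(x, 1L, max)
  e <- exp(x - mx)
  e[is.na(e)] <- 0  # rows where everything is masked
  e / pmax(rowSums(e), .Machine$double.xmin)
}

# layer normalization over each row, with gain g and bias b (1 x d params)
op_layernorm <- function(tape, a, g, b, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  v <- sweep(sweep(xhat, 2L, g$val[1L, ], "*"), 2L, b$val[1L, ], "+")
  node <- td_node(tape, v)
  node$bw <- function(self) {
    gr <- self$grad
    .td_acc(g, matrix(colSums(gr * xhat), 1L))
    .td_acc(b, matrix(colSums(gr), 1L))
    gx <- sweep(gr, 2L, g$val[1L, ], "*")
    # d/dx of row-wise layernorm
    term <- gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)
    .td_acc(a, term * istd)
  }
  node
}

## ---- fused sequence ops ----

# LSTM cell, fused. x: batch x in, hc_prev: batch x 2H (h then c),
# W: (in+H) x 4H, b: 1 x 4H, mask: length-batch 0/1 vector (1 = real token;
# at 0 the state passes through unchanged). Gate order: i, f, o, g.
# Returns a node whose val is cbind(h, c).
op_lstm_cell <- function(tape, x, hc_prev, W, b, mask = NULL) {
  H <- ncol(hc_prev$val) / 2L
  h_prev <- hc_prev$val[, seq_len(H), drop = FALSE]
  c_prev <- hc_prev$val[, H + seq_len(H), drop = FALSE]
  fwd <- .lstm_cell_fwd(x$val, h_prev, c_prev, W$val, b$val, mask)
  node <- td_node(tape, cbind(fwd$h, fwd$c))
  node$bw <- function(self) {
    gh <- self$grad[, seq_len(H), drop = FALSE]
    gc <- self$grad[, H + seq_len(H), drop = FALSE]
    m <- if (is.null(mask)) 1 else mask
    dh_new <- gh * m
    dh_prev <- gh * (1 - m)
    dc_new <- gc * m
    dc_prev <- gc * (1 - m)
    tc <- tanh(fwd$c_new)
    do_ <- dh_new * tc
    dc_new <- dc_new + dh_new * fwd$o * (1 - tc * tc)
    df <- dc_new * c_prev
    dc_prev <- dc_prev + dc_new * fwd$f
    di <- dc_new * fwd$g
    dg <- dc_new * fwd$i
    dz <- cbind(di * fwd$i * (1 - fwd$i),
                df * fwd$f * (1 - fwd$f),
                do_ * fwd$o * (1 - fwd$o),
                dg * (1 - fwd$g * fwd$g))
    xh <- cbind(x$val, h_prev)
    .td_acc(W, crossprod(xh, dz))
    .td_acc(b, matrix(colSums(dz), 1L))
    dxh <- dz %*% t(W$val)
    nin <- ncol(x$val)
    .td_acc(x, dxh[, seq_len(nin), drop = FALSE])
    ghc <- cbind(dxh[, nin + seq_len(H), drop = FALSE] + dh_prev,
                 dc_prev)
    .td_acc(hc_prev, ghc)
  }
  node
}

# shared forward math for the fused op and the no-tape inference path
.lstm_cell_fwd <- function(x, h_prev, c_prev, W, b, mask = NULL) {
  H <- ncol(h_prev)
  z <- sweep(cbind(x, h_prev) %*% W, 2L, b[1L, ], "+")
  i <- .sigmoid(z[, seq_len(H), drop = FALSE])
  f <- .sigmoid(z[, H + seq_len(H), drop = FALSE])
  o <- .sigmoid(z[, 2L * H + seq_len(H), drop = FALSE])
  g <- tanh(z[, 3L * H + seq_len(H), drop = FALSE])
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  if (is.null(mask)) {
    h <- h_new; c <- c_new
  } else {
    h <- mask * h_new + (1 - mask) * h_prev
    c <- mask * c_new + (1 - mask) * c_prev
  }
  list(h = h, c = c, i = i, f = f, o = o, g = g, c_new = c_new)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Luong general attention scores, fused. s: batch x Hs (current decoder
# state), Hcat: batch x (m*He) (encoder states, position-major blocks),
# Wa: Hs x He. score[b, i] = s[b, ] %*% Wa %*% H_i[b, ].
op_general_scores <- function(tape, s, Hcat, Wa, m) {
  He <- ncol(Hcat$val) / m
  A <- s$val %*% Wa$val                                  # batch x He
  sc <- matrix(0, nrow(s$val), m)
  for (i in seq_len(m)) {
    sc[, i] <- rowSums(A * Hcat$val[, (i - 1L) * He + seq_len(He), drop = FALSE])
  }
  node <- td_node(tape, sc)
  node$bw <- function(self) {
    gA <- matrix(0, nrow(A), ncol(A))
    gH <- matrix(0, nrow(Hcat$val), ncol(Hcat$val))
    for (i in seq_len(m)) {
      cols <- (i - 1L) * He + seq_len(He)
      Hi <- Hcat$val[, cols, drop = FALSE]
      gi <- self$grad[, i]
      gA <- gA + gi * Hi
      gH[, cols] <- gi * A
    }
    .td_acc(Hcat, gH)
    .td_acc(Wa, crossprod(s$val, gA))
    .td_acc(s, gA %*% t(Wa$val))
  }
  node
}

# Bahdanau additive attention scores, fused.
# score[b, i] = va' tanh(Wa s[b, ] + Ua H_i[b, ]).
# s: batch x Hs, Hcat: batch x (m*He), Wa: Hs x d, Ua: He x d, va: d x 1.
op_soft_scores <- function(tape, s, Hcat, Wa, Ua, va, m) {
  batch <- nrow(s$val)
  He <- ncol(Hcat$val) / m
  A <- s$val %*% Wa$val                                  # batch x d
  # stack positions: rows (i-1)*batch + b
  Hr <- matrix(0, m * batch, He)
  for (i in seq_len(m)) {
    Hr[(i - 1L) * batch + seq_len(batch), ] <-
      Hcat$val[, (i - 1L) * He + seq_len(He), drop = FALSE]
  }
  U <- Hr %*% Ua$val                                     # (m*batch) x d
  Arep <- A[rep(seq_len(batch), m), , drop = FALSE]
  T_ <- tanh(U + Arep)
  scv <- T_ %*% va$val                                   # (m*batch) x 1
  sc <- matrix(scv, batch, m)                            # column i = position i
  node <- td_node(tape, sc)
  node$bw <- function(self) {
    gsc <- matrix(self$grad, m * batch, 1L)
    gT <- (gsc %*% t(va$val)) * (1 - T_ * T_)
    .td_acc(va, crossprod(T_, gsc))
    .td_acc(Ua, crossprod(Hr, gT))
    gHr <- gT %*% t(Ua$val)
    gH <- matrix(0, batch, m * He)
    gA <- matrix(0, batch, ncol(A))
    for (i in seq_len(m)) {
      rows <- (i - 1L) * batch + seq_len(batch)
      gH[, (i - 1L) * He + seq_len(He)] <- gHr[rows, , drop = FALSE]
      gA <- gA + gT[rows, , drop = FALSE]
    }
    .td_acc(Hcat, gH)
    .td_acc(Wa, crossprod(s$val, gA))
    .td_acc(s, gA %*% t(Wa$val))
  }
  node
}

# attention context: ctx[b, ] = sum_i alpha[b, i] * H_i[b, ]
op_attn_context <- function(tape, alpha, Hcat, m) {
  He <- ncol(Hcat$val) / m
  ctx <- matrix(0, nrow(alpha$val), He)
  for (i in seq_len(m)) {
    ctx <- ctx + alpha$val[, i] *
      Hcat$val[, (i - 1L) * He + seq_len(He), drop = FALSE]
  }
  node <- td_node(tape, ctx)
  node$bw <- function(self) {
    ga <- matrix(0, nrow(alpha$val), m)
    gH <- matrix(0, nrow(Hcat$val), ncol(Hcat$val))
    for (i in seq_len(m)) {
      cols <- (i - 1L) * He + seq_len(He)
      Hi <- Hcat$val[, cols, drop = FALSE]
      ga[, i] <- rowSums(self$grad * Hi)
      gH[, cols] <- alpha$val[, i] * self$grad
    }
    .td_acc(alpha, ga)
    .td_acc(Hcat, gH)
  }
  node
}

# mean weighted softmax cross-entropy. logits: n x V, targets: length-n
# integer class indices, weights: length-n nonnegative (0 = padding).
op_softmax_xent <- function(tape, logits, targets, weights) {
  probs <- .softmax_rows(logits$val)
  n <- length(targets)
  wsum <- sum(weights)
  picked <- probs[cbind(seq_len(n), targets)]
  loss <- sum(-log(pmax(picked, 1e-12)) * weights) / max(wsum, 1)
  node <- td_node(tape, matrix(loss, 1L, 1L))
  node$probs <- probs
  node$bw <- function(self) {
    g <- probs * weights
    g[cbind(seq_len(n), targets)] <- g[cbind(seq_len(n), targets)] - weights
    .td_acc(logits, self$grad[1L, 1L] * g / max(wsum, 1))
  }
  node
}

# multi-head scaled-dot attention, fused; loops over batch sequences.
# q, k, v: (batch*mq|mk) x d nodes laid out sequence-major (rows of
# sequence b are (b-1)*m + 1:m). n_heads divides d. mask: mq x mk additive
# matrix (0 / -Inf) applied to every sequence, or NULL.
# Returns node (batch*mq) x d; node$attn holds the head-averaged weights
# (list per sequence, mq x mk).
op_multihead_attn <- function(tape, q, k, v, batch, mq, mk, n_heads,
                              mask = NULL) {
  d <- ncol(q$val)
  dk <- d %/% n_heads
  out <- matrix(0, batch * mq, d)
  caches <- vector("list", batch)
  attn_avg <- vector("list", batch)
  for (b in seq_len(batch)) {
    rq <- (b - 1L) * mq + seq_len(mq)
    rk <- (b - 1L) * mk + seq_len(mk)
    mb <- if (is.list(mask)) mask[[b]] else mask
    hc <- vector("list", n_heads)
    aavg <- matrix(0, mq, mk)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      Qh <- q$val[rq, cols, drop = FALSE]
      Kh <- k$val[rk, cols, drop = FALSE]
      Vh <- v$val[rk, cols, drop = FALSE]
      sc <- Qh %*% t(Kh) / sqrt(dk)
      al <- .softmax_rows(sc, mb)
      out[rq, cols] <- al %*% Vh
      hc[[h]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, al = al)
      aavg <- aavg + al / n_heads
    }
    caches[[b]] <- hc
    attn_avg[[b]] <- aavg
  }
  node <- td_node(tape, out)
  node$attn <- attn_avg
  node$bw <- function(self) {
    gq <- matrix(0, nrow(q$val), d)
    gk <- matrix(0, nrow(k$val), d)
    gv <- matrix(0, nrow(v$val), d)
    for (b in seq_len(batch)) {
      rq <- (b - 1L) * mq + seq_len(mq)
      rk <- (b - 1L) * mk + seq_len(mk)
      for (h in seq_len(n_heads)) {
        cols <- (h - 1L) * dk + seq_len(dk)
        cc <- caches[[b]][[h]]
        go <- self$grad[rq, cols, drop = FALSE]
        gal <- go %*% t(cc$Vh)
        gv[rk, cols] <- gv[rk, cols] + crossprod(cc$al, go)
        gsc <- (gal - rowSums(gal * cc$al)) * cc$al / sqrt(dk)
        gq[rq, cols] <- gq[rq, cols] + gsc %*% cc$Kh
        gk[rk, cols] <- gk[rk, cols] + crossprod(gsc, cc$Qh)
      }
    }
    .td_acc(q, gq)
    .td_acc(k, gk)
    .td_acc(v, gv)
  }
  node
}

## ---- Adam optimizer ----

adam_state <- function(params) {
  list(params = params,
       m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

adam_step <- function(opt, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  opt$t <- opt$t + 1L
  # global gradient-norm clipping
  sq <- 0
  for (p in opt$params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
  gn <- sqrt(sq)
  scale <- if (gn > clip) clip / gn else 1
  for (j in seq_along(opt$params)) {
    p <- opt$params[[j]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    opt$m[[j]] <- beta1 * opt$m[[j]] + (1 - beta1) * g
    opt$v[[j]] <- beta2 * opt$v[[j]] + (1 - beta2) * g * g
    mhat <- opt$m[[j]] / (1 - beta1^opt$t)
    vhat <- opt$v[[j]] / (1 - beta2^opt$t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
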