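test_that("attention score primitives match hand-rolled linear algebra", {
  # zero va: every additive score 0 -> uniform weights
  Wa <- matrix(rnorm(6), 3, 2); Ua <- matrix(rnorm(12), 3, 4)
  expect_equal(soft_attention_score(rnorm(2), rnorm(4), Wa, Ua, rep(0, 3)), 0)
  expect_equal(attention_weights(c(0, 0, 0, 0)), rep(0.25, 4))
  # single encoder position -> softmax of singleton is exactly 1
  expect_equal(attention_weights(2.7), 1)

  set.seed(11)
  for (rep_i in 1:10) {
    s <- rnorm(3); h <- rnorm(4); va <- rnorm(5)
    Wa <- matrix(rnorm(15), 5, 3); Ua <- matrix(rnorm(20), 5, 4)
    manual <- 0
    for (k in 1:5) {
      manual <- manual + va[k] * tanh(sum(Wa[k, ] * s) + sum(Ua[k, ] * h))
    }
    expect_equal(soft_attention_score(s, h, Wa, Ua, va), manual)

    W2 <- matrix(rnorm(12), 3, 4)
    manual2 <- 0
    for (a in 1:3) for (b in 1:4) manual2 <- manual2 + s[a] * W2[a, b] * h[b]
    expect_equal(general_attention_score(s, h, W2), manual2)
  }

  # general attention: identity weight, orthogonal / aligned unit vectors
  expect_equal(general_attention_score(c(1, 0), c(0, 1), diag(2)), 0)
  expect_equal(general_attention_score(c(1, 0), c(1, 0), diag(2)), 1)
})

test_that("scaled dot-product attention matches brute force and edge cases", {
  # one key: output is exactly the single value row
  Q <- matrix(rnorm(6), 2, 3); K <- matrix(rnorm(3), 1, 3)
  V <- matrix(c(5, -2), 1, 2)
  r <- scaled_dot_attention(Q, K, V)
  expect_equal(r$output, rbind(V[1, ], V[1, ]), ignore_attr = TRUE)
  expect_equal(as.numeric(r$weights), c(1, 1))

  # orthonormal Q=K at a large scale approaches identity-weighted V
  Q <- diag(3) * 50
  V <- matrix(rnorm(9), 3, 3)
  r <- scaled_dot_attention(Q, Q, V)
  expect_lt(max(abs(r$output - V)), 1e-8)

  set.seed(12)
  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(6), 3, 2)
  r <- scaled_dot_attention(Q, K, V)
  sc <- Q %*% t(K) / sqrt(4)
  w <- t(apply(sc, 1, function(x) exp(x - max(x)) / sum(exp(x - max(x)))))
  expect_equal(r$weights, w, tolerance = 1e-12)
  expect_equal(r$output, w %*% V, tolerance = 1e-12)
  expect_equal(rowSums(r$weights), rep(1, 3))
  expect_error(scaled_dot_attention(Q, K[, 1:2], V), "key dimension")
})

test_that("model configuration enforces the architecture/attention pairing", {
  expect_error(model_config("lstm", "self"), "self")
  expect_error(model_config("transformer", "general"), "self")
  expect_silent(model_config("brnn", "soft"))
  cfg <- model_config("transformer")
  expect_equal(cfg$attention, "self")
})

test_that("step outputs are normalized distributions for every architecture", {
  fix <- tiny_corpus()
  for (spec in list(c("lstm", "general"), c("lstm", "soft"), c("lstm", "none"),
                    c("brnn", "general"), c("brnn", "soft"),
                    c("transformer", "self"))) {
    m <- tiny_model(fix, spec[1], spec[2])
    st0 <- ms_encode(m, fix$pairs[[1]]$source)
    st <- ms_step(m, st0, "<s>")
    # log-probabilities normalize: logsumexp == 0
    expect_lt(abs(log(sum(exp(st$logp)))), 1e-5)
    expect_equal(sum(st$attn), 1, tolerance = 1e-5)
    expect_true(all(st$attn >= 0))
    if (spec[2] == "none") {
      expect_false(isTRUE(attr(st$attn, "informative")))
    }
    # advancing the same state twice with the same token is identical
    st2 <- ms_step(m, st0, "<s>")
    expect_identical(st$logp, st2$logp)
    expect_identical(st$attn, st2$attn)
  }
})

test_that("over-length sources are rejected at encode time", {
  fix <- tiny_corpus()
  m <- tiny_model(fix, "lstm", "general")
  expect_error(ms_encode(m, rep("D00001", 46)), "max_source_len")
})

test_that("stepwise scoring agrees with the teacher-forced training loss", {
  fix <- tiny_corpus()
  for (spec in list(c("lstm", "general"), c("lstm", "soft"),
                    c("brnn", "general"), c("transformer", "self"))) {
    m <- tiny_model(fix, spec[1], spec[2])
    p <- fix$pairs[[3]]
    ll <- sequence_log_likelihood(m, p$source, p$target)
    tape <- mortseq:::td_tape()
    loss <- mortseq:::.batch_loss(
      m, tape,
      list(vocab_encode(m$src_vocab, p$source)),
      list(vocab_encode(m$tgt_vocab, p$target)))
    # loss is mean negative log-probability over len(target)+1 steps
    expect_equal(ll, -loss$val[1, 1] * (length(p$target) + 1), tolerance = 1e-4)
  }
})

test_that("training reduces the loss and is reproducible from the seed", {
  fix <- tiny_corpus(n = 50)
  cfg <- model_config("lstm", "general", hidden_size = 16L,
                      train_steps = 120L, batch_size = 16L, seed = 33)
  m1 <- train_model(fix$pairs, fix$sv, fix$tv, cfg)
  expect_lt(m1$final_loss, m1$log$loss[1])
  m2 <- train_model(fix$pairs, fix$sv, fix$tv, cfg)
  expect_identical(m1$final_loss, m2$final_loss)
  probe <- fix$pairs[1:5]
  out1 <- lapply(probe, function(p) greedy_decode(m1, p$source)$tokens)
  out2 <- lapply(probe, function(p) greedy_decode(m2, p$source)$tokens)
  expect_identical(out1, out2)
  expect_error(train_model(list(), fix$sv, fix$tv, cfg), "empty")
})

test_that("a copy task is learnable to high sequence accuracy", {
  # target = first two source tokens: trivially learnable alignment
  set.seed(44)
  toks <- sprintf("K%02d", 1:10)
  pairs <- lapply(1:240, function(i) {
    s <- sample(toks, 4)
    seq_pair(s, s[1:2])
  })
  sv <- build_vocabulary(lapply(pairs, function(p) p$source))
  tv <- build_vocabulary(lapply(pairs, function(p) p$target))
  cfg <- model_config("lstm", "general", hidden_size = 32L, num_layers = 1L,
                      train_steps = 700L, batch_size = 32L, seed = 45)
  m <- train_model(pairs, sv, tv, cfg)
  hit <- vapply(pairs[1:50], function(p)
    identical(greedy_decode(m, p$source)$tokens, p$target), logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("checkpoint round trip preserves outputs bit for bit", {
  fix <- tiny_corpus()
  m <- tiny_model(fix, "lstm", "soft", train_steps = 30L)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  src <- fix$pairs[[2]]$source
  s1 <- ms_step(m, ms_encode(m, src), "<s>")
  s2 <- ms_step(m2, ms_encode(m2, src), "<s>")
  expect_identical(s1$logp, s2$logp)
  expect_identical(s1$attn, s2$attn)
  expect_identical(greedy_decode(m, src), greedy_decode(m2, src))
  expect_error(suppressWarnings(load_model(withr::local_tempfile(fileext = ".rds"))))
})

test_that("training log is written as TSV", {
  fix <- tiny_corpus(n = 30)
  m <- tiny_model(fix, "lstm", "general", train_steps = 20L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_training_log(m, f)
  log <- utils::read.delim(f)
  expect_equal(names(log), c("step", "loss"))
  expect_equal(log$step[nrow(log)], 20)
})
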