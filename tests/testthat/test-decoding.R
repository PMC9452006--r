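test_that("greedy decoding follows a rigged near-deterministic model", {
  tm <- toy_model(n_tokens = 4, seed = 1)
  # rig: from <s> always T01, from T01 always T02, from T02 always </s>
  tm$logp[] <- log(1e-9)
  rig <- function(prev, nxt) {
    i <- tm$tgt_vocab$index[[prev]]; j <- tm$tgt_vocab$index[[nxt]]
    tm$logp[i, ] <<- log(1e-9); tm$logp[i, j] <<- log(1 - 1e-5)
  }
  rig("<s>", "T01"); rig("T01", "T02"); rig("T02", "</s>")
  out <- greedy_decode(tm, c("X", "Y"))
  expect_equal(out$tokens, c("T01", "T02"))
  expect_equal(dim(out$attention), c(2L, 2L))

  # max_length 1 -> at most a single code
  out1 <- greedy_decode(tm, c("X", "Y"), max_length = 1)
  expect_equal(out1$tokens, "T01")
})

test_that("beam search with k = 1 equals greedy decoding on random models", {
  for (s in 1:100) {
    tm <- toy_model(n_tokens = 5, seed = s)
    src <- sprintf("S%d", seq_len(1 + s %% 4))
    g <- greedy_decode(tm, src, max_length = 4)
    b <- beam_search(tm, src, beam_config(k = 1, max_length = 4))
    expect_identical(b$tokens, g$tokens)
    expect_equal(b$score, g$score, tolerance = 1e-12)
  }
})

test_that("beam search equals exhaustive enumeration on toy instances", {
  for (s in c(2, 7, 19)) {
    tm <- toy_model(n_tokens = 4, seed = s)
    best <- oracle_exhaustive_best(tm, c("A", "B"), max_length = 3)
    b <- beam_search(tm, c("A", "B"),
                     beam_config(k = 200, max_length = 3))
    expect_equal(b$tokens, best$tokens)
    expect_equal(b$score, best$score, tolerance = 1e-10)
  }
})

test_that("the best beam score is monotone in beam size", {
  for (s in 1:20) {
    tm <- toy_model(n_tokens = 6, seed = 100 + s)
    prev <- -Inf
    for (k in c(1, 2, 4, 8)) {
      b <- beam_search(tm, "A", beam_config(k = k, max_length = 4))
      expect_gte(b$score, prev - 1e-12)
      prev <- b$score
    }
  }
})

test_that("knowledge constraint restricts successors and falls back as configured", {
  g <- build_knowledge_graph(
    data.frame(cause_low = "T01", cause_high = "T01", effect = "T02"),
    c("T01", "T02", "T03"))
  expect_error(beam_search(toy_model(), "A",
                           beam_config(constrained = TRUE)), "requires")

  for (s in 1:20) {
    tm <- toy_model(n_tokens = 3, seed = 200 + s)
    b <- beam_search(tm, "A",
                     beam_config(k = 3, max_length = 4, constrained = TRUE),
                     graph = g)
    if (length(b$tokens) >= 2) {
      for (i in seq_len(length(b$tokens) - 1)) {
        expect_true(is_valid_pair(g, b$tokens[i], b$tokens[i + 1]))
      }
    }
    # force_end: T02 and T03 have no successors, so nothing may follow them
    if (length(b$tokens) >= 1) {
      last <- b$tokens[length(b$tokens)]
      expect_true(last %in% c("T01", "T02", "T03"))
    }
  }

  # unconstrained_step fallback may emit non-edges after a dead-end code
  tm <- toy_model(n_tokens = 3, seed = 201)
  tm$logp[] <- log(1e-9)
  for (prev in c("<s>", "T01", "T02", "T03")) {
    i <- tm$tgt_vocab$index[[prev]]
    tm$logp[i, ] <- log(1e-9)
  }
  tm$logp[tm$tgt_vocab$index[["<s>"]], tm$tgt_vocab$index[["T02"]]] <- log(0.999)
  tm$logp[tm$tgt_vocab$index[["T02"]], tm$tgt_vocab$index[["T03"]]] <- log(0.999)
  tm$logp[tm$tgt_vocab$index[["T03"]], tm$tgt_vocab$index[["</s>"]]] <- log(0.999)
  soft <- beam_search(tm, "A",
                      beam_config(k = 1, max_length = 3, constrained = TRUE,
                                  constraint_fallback = "unconstrained_step"),
                      graph = g)
  expect_equal(soft$tokens, c("T02", "T03"))  # T02 -> T03 is NOT an edge
  hard <- beam_search(tm, "A",
                      beam_config(k = 1, max_length = 3, constrained = TRUE,
                                  constraint_fallback = "force_end"),
                      graph = g)
  expect_equal(hard$tokens, "T02")            # forced to end at the dead end
})

test_that("constrained decoding of a real untrained model emits only graph edges", {
  fix <- tiny_corpus(n = 40)
  m <- tiny_model(fix, "lstm", "general")
  bc <- beam_config(k = 2, max_length = 6, constrained = TRUE,
                    constraint_fallback = "force_end")
  for (p in fix$pairs[1:25]) {
    out <- beam_search(m, p$source, bc, graph = fix$world$graph)
    if (length(out$tokens) >= 2) {
      for (i in seq_len(length(out$tokens) - 1)) {
        expect_true(is_valid_pair(fix$world$graph,
                                  out$tokens[i], out$tokens[i + 1]))
      }
    }
  }
})

test_that("beam attention rows align with emitted tokens", {
  fix <- tiny_corpus(n = 40)
  m <- tiny_model(fix, "lstm", "soft", train_steps = 30L)
  p <- fix$pairs[[1]]
  out <- beam_search(m, p$source, beam_config(k = 3, max_length = 5))
  expect_equal(nrow(out$attention), length(out$tokens))
  expect_equal(ncol(out$attention), length(p$source))
  if (nrow(out$attention) > 0)
    expect_equal(unname(rowSums(out$attention)),
                 rep(1, nrow(out$attention)), tolerance = 1e-5)
})

test_that("translations are written one sequence per line with a sidecar", {
  fix <- tiny_corpus(n = 20)
  m <- tiny_model(fix, "lstm", "general", train_steps = 20L)
  res <- translate_sequences(m, lapply(fix$pairs[1:5], function(p) p$source),
                             beam_config(k = 2, max_length = 4))
  f <- withr::local_tempfile(); fs <- withr::local_tempfile()
  write_translations(res, f, fs)
  lines <- readLines(f)
  expect_length(lines, 5)
  expect_equal(strsplit(lines[1], " ")[[1]][seq_along(res[[1]]$tokens)],
               res[[1]]$tokens)
  side <- readLines(fs)
  expect_equal(side[1], "index\tscore\tattention_row_major")
  expect_length(side, 6)
})
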