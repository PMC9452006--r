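test_that("modified precision reproduces the worked 1-/2-gram example", {
  cand <- c("R909", "J189", "J969")
  ref <- c("R909", "J189", "J960")
  p1 <- modified_precision(cand, ref, 1)
  expect_equal(p1$numerator, 2L); expect_equal(p1$denominator, 3L)
  expect_equal(p1$value, 2 / 3)
  p2 <- modified_precision(cand, ref, 2)
  expect_equal(p2$numerator, 1L); expect_equal(p2$denominator, 2L)
  expect_equal(p2$value, 1 / 2)
  # identity: candidate == reference
  expect_equal(modified_precision(ref, ref, 2)$value, 1)
  # clipping: repeated candidate code cannot out-count the reference
  expect_equal(modified_precision(c("A", "A", "A"), c("A", "B"), 1)$value, 1 / 3)
  # candidate shorter than the gram order is flagged undefined
  expect_false(modified_precision("A", ref, 2)$defined)
  expect_error(modified_precision(cand, ref, 0), "gram order")
})

test_that("brevity penalty follows the piecewise definition", {
  expect_equal(brevity_penalty(3, 3), 1)          # equal lengths: exp(0)
  expect_equal(brevity_penalty(4, 2), 1)          # candidate longer
  expect_equal(brevity_penalty(1, 2), exp(-1))    # short candidate
  expect_equal(brevity_penalty(2, 5), exp(1 - 5 / 2))
  expect_error(brevity_penalty(0, 3), "positive")
})

test_that("bleu reproduces the published candidate-sequence scores", {
  b <- bleu(c("R909", "J189", "J969"), c("R909", "J189", "J960"))
  expect_equal(b$p, c(2 / 3, 1 / 2))
  expect_equal(b$BP, 1)
  expect_equal(round(b$score, 2), 0.47)
  expect_equal(b$score, (2 / 3) * sqrt(1 / 2))  # harmonic weights 1, 1/2

  ref <- c("I251", "I38", "I429", "I469")
  cands <- list(c("I429", "I38", "I469", "I251"),
                c("I38", "I429", "I251", "I469"),
                c("I429", "I469", "I251", "I38"),
                c("I38", "I429", "I469", "I251"),
                ref)
  expected <- c(0.0, 57.7, 81.6, 81.6, 100.0)
  got <- vapply(cands, function(cd) round(100 * bleu(cd, ref)$score, 1),
                numeric(1))
  expect_equal(got, expected)
})

test_that("bleu identity, range and degenerate-length handling", {
  set.seed(55)
  for (i in 1:50) {
    y <- sample(LETTERS, sample(1:6, 1), replace = TRUE)
    expect_equal(bleu(y, y)$score, 1)
  }
  b <- bleu("A", c("A", "B"))  # single-code candidate: 1-gram + BP only
  expect_true(b$degenerate)
  expect_equal(b$N_effective, 1L)
  expect_equal(b$score, 1 * exp(1 - 2))
  expect_equal(bleu("A", "A")$score, 1)
  expect_error(bleu(character(0), "A"), "non-empty")
})

test_that("bleu matches the brute-force oracle on random pairs", {
  set.seed(56)
  for (i in 1:300) {
    cand <- sample(LETTERS[1:8], sample(2:6, 1), replace = TRUE)
    ref <- sample(LETTERS[1:8], sample(2:6, 1), replace = TRUE)
    expect_equal(bleu(cand, ref)$score, oracle_bleu(cand, ref),
                 tolerance = 1e-9)
  }
})

test_that("candidates with identical code multisets rank by preserved adjacencies", {
  ref <- c("I251", "I38", "I429", "I469")
  perm_score <- function(cd) bleu(cd, ref)$score
  # all permutations have p1 = 1; score ordering follows 2-gram overlap
  s2 <- perm_score(c("I38", "I429", "I251", "I469"))  # 1 adjacent pair kept
  s3 <- perm_score(c("I429", "I469", "I251", "I38"))  # 2 adjacent pairs kept
  s5 <- perm_score(ref)                               # all 3 kept
  expect_true(s2 < s3 && s3 < s5)
  expect_equal(bleu(c("I38", "I429", "I251", "I469"), ref)$p[1], 1)
})

test_that("accuracy metrics match their definitions", {
  gen <- list(c("A", "B"), c("B", "A"), c("C"))
  ref <- list(c("A", "B"), c("A", "B"), c("D"))
  expect_equal(entire_sequence_accuracy(gen, ref), 100 / 3)
  # multiset recall: 1, 1, 0 -> 66.7
  expect_equal(individual_codes_accuracy(gen, ref), 100 * 2 / 3)
  expect_equal(underlying_cod_accuracy(gen, ref), 100 / 3)
  expect_equal(entire_sequence_accuracy(ref, ref), 100)
  expect_equal(underlying_cod_accuracy(list("X"), list(c("Y", "X"))), 0)
  expect_error(entire_sequence_accuracy(gen, ref[1:2]), "differ")

  # permutations score 1 on order-free accuracy, 0 overlap scores 0
  expect_equal(individual_codes_accuracy(list(c("B", "A")), list(c("A", "B"))), 100)
  expect_equal(individual_codes_accuracy(list(c("X", "Y")), list(c("A", "B"))), 0)

  # exact match implies individual score 1 and first-code match
  set.seed(57)
  for (i in 1:20) {
    y <- sample(LETTERS, sample(1:4, 1))
    expect_equal(individual_codes_accuracy(list(y), list(y)), 100)
    expect_equal(underlying_cod_accuracy(list(y), list(y)), 100)
  }
})

test_that("random-pair accuracies match brute-force counting", {
  set.seed(58)
  gen <- lapply(1:40, function(i) sample(LETTERS[1:5], sample(1:4, 1), replace = TRUE))
  ref <- lapply(1:40, function(i) sample(LETTERS[1:5], sample(1:4, 1), replace = TRUE))
  exact <- 0; und <- 0; indiv <- 0
  for (i in 1:40) {
    if (length(gen[[i]]) == length(ref[[i]]) && all(gen[[i]] == ref[[i]]))
      exact <- exact + 1
    if (gen[[i]][1] == ref[[i]][1]) und <- und + 1
    hits <- 0; pool <- ref[[i]]
    for (g in gen[[i]]) {
      j <- match(g, pool)
      if (!is.na(j)) { hits <- hits + 1; pool <- pool[-j] }
    }
    indiv <- indiv + hits / length(ref[[i]])
  }
  expect_equal(entire_sequence_accuracy(gen, ref), 100 * exact / 40)
  expect_equal(underlying_cod_accuracy(gen, ref), 100 * und / 40)
  expect_equal(individual_codes_accuracy(gen, ref), 100 * indiv / 40)
})

test_that("evaluate_run and cross-fold aggregation match manual computation", {
  gen <- list(c("A", "B"), c("A", "C"), "D")
  ref <- list(c("A", "B"), c("A", "B"), "D")
  rep <- evaluate_run(gen, ref)
  manual_bleus <- c(1, bleu(c("A", "C"), c("A", "B"))$score, 1)
  expect_equal(rep$bleu_mean, 100 * mean(manual_bleus))
  expect_equal(rep$bleu_std, 100 * sd(manual_bleus))
  expect_equal(rep$entire_sequence_accuracy, 200 / 3)
  expect_equal(rep$individual_codes_accuracy, 100 * mean(c(1, 0.5, 1)))
  expect_equal(rep$underlying_cod_accuracy, 100)
  expect_equal(rep$n_pairs, 3L)

  # single identical pair: everything 100
  one <- evaluate_run(list(c("A", "B")), list(c("A", "B")))
  expect_equal(one$bleu_mean, 100)
  expect_equal(one$entire_sequence_accuracy, 100)

  # five identical folds aggregate with zero standard deviation
  cf <- cross_fold_report(replicate(5, rep, simplify = FALSE))
  expect_equal(cf$sd, rep(0, 4))
  expect_equal(cf$mean[cf$metric == "bleu_mean"], rep$bleu_mean)

  # file-based path
  fg <- withr::local_tempfile(); fr <- withr::local_tempfile()
  writeLines(c("A B", "A C", "D"), fg)
  writeLines(c("A B", "A B", "D"), fr)
  rep2 <- evaluate_run(fg, fr)
  expect_equal(rep2$bleu_mean, rep$bleu_mean)

  # JSON report round trip
  fj <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, json_path = fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$bleu_mean, rep$bleu_mean)
})
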