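test_that("ICD normalization strips dots, uppercases, and is idempotent", {
  expect_equal(normalize_icd("J44.9"), "J449")
  expect_equal(normalize_icd(c("i25.1", " I38 ")), c("I251", "I38"))
  x <- c("J44.9", "e11.9", "I509")
  expect_identical(normalize_icd(normalize_icd(x)), normalize_icd(x))
  expect_error(normalize_icd(""), "empty")
})

test_that("decedent records enforce the 45/18 length bounds", {
  r <- decedent_record("d1", c("I251", "I38", "R000"), c("I251", "I469"))
  expect_length(r$diagnoses, 3)
  expect_equal(r$cod_sequence[1], "I251")
  expect_error(decedent_record("d2", rep("A000", 46), "I251"), "1-45")
  expect_error(decedent_record("d3", "A000", rep("I10", 19)), "1-18")
  expect_error(decedent_record("d4", "A000", character(0)))
})

test_that("decedent CSV parses pipe-separated code lists and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,diagnoses,cod_sequence",
               "d1,I251|I38|R000,I251|I469",
               "d2,J44.9,J449"), f)
  recs <- read_decedent_records(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$diagnoses, c("I251", "I38", "R000"))
  expect_equal(recs[[1]]$cod_sequence, c("I251", "I469"))
  expect_equal(recs[[2]]$diagnoses, "J449")  # normalized on read

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,diagnoses,cod_sequence",
               paste0("bad,", paste(rep("A000", 46), collapse = "|"), ",I10")),
             f2)
  expect_error(read_decedent_records(f2), "row 1")
  expect_error(read_decedent_records("no/such/file.csv"), "no such file")
})

test_that("decedent CSV round trip is lossless on 100 synthetic records", {
  w <- generate_world(synthetic_config(seed = 21))
  cp <- generate_corpus(w, 100, seed = 22)
  f <- withr::local_tempfile(fileext = ".csv")
  write_decedent_records(cp$records, f)
  back <- read_decedent_records(f)
  expect_equal(lapply(back, unclass), lapply(cp$records, unclass))
})

test_that("parallel corpus writes space-joined lines and round trips", {
  pairs <- list(seq_pair(c("I251", "I38"), c("I251", "I469")))
  fs <- withr::local_tempfile(); ft <- withr::local_tempfile()
  write_parallel_corpus(pairs, fs, ft)
  expect_equal(readLines(fs), "I251 I38")
  expect_equal(readLines(ft), "I251 I469")

  set.seed(31)
  rnd <- lapply(1:1000, function(i) {
    seq_pair(sample(LETTERS, sample(1:6, 1), replace = TRUE),
             sample(LETTERS, sample(1:3, 1), replace = TRUE))
  })
  write_parallel_corpus(rnd, fs, ft)
  back <- read_parallel_corpus(fs, ft)
  expect_equal(lapply(back, unclass), lapply(rnd, unclass))

  # empty pair list -> two empty files
  write_parallel_corpus(list(), fs, ft)
  expect_length(readLines(fs), 0)
  expect_length(read_parallel_corpus(fs, ft), 0)
})

test_that("parallel corpus readers report mismatches and blank lines", {
  fs <- withr::local_tempfile(); ft <- withr::local_tempfile()
  writeLines(c("A B", "C"), fs); writeLines("X", ft)
  expect_error(read_parallel_corpus(fs, ft), "2.*1")
  writeLines(c("A", ""), fs); writeLines(c("X", "Y"), ft)
  expect_error(read_parallel_corpus(fs, ft), "blank.*2")
})

test_that("vocabulary orders tokens by frequency then lexicographically", {
  v <- build_vocabulary(list(c("A", "B"), "A"))
  expect_equal(v$tokens, c("<pad>", "<s>", "</s>", "<unk>", "A", "B"))
  expect_equal(unname(v$index[c("<pad>", "<s>", "</s>", "<unk>")]), 1:4)
  v2 <- build_vocabulary(list(c("A", "B"), "A"), min_count = 2)
  expect_equal(v2$tokens, c("<pad>", "<s>", "</s>", "<unk>", "A"))
  expect_error(build_vocabulary(list()), "empty")

  # ties broken lexicographically
  v3 <- build_vocabulary(list(c("Z9", "A1")))
  expect_equal(v3$tokens[5:6], c("A1", "Z9"))

  # unknown tokens map to <unk> and decode back
  ids <- vocab_encode(v, c("A", "QQQ"))
  expect_equal(ids, c(5L, 4L))
  expect_equal(vocab_decode(v, ids), c("A", "<unk>"))

  f <- withr::local_tempfile()
  write_vocabulary(v, f)
  expect_equal(read_vocabulary(f)$tokens, v$tokens)
})

test_that("vocabulary token set matches the generator's emitted tokens", {
  w <- generate_world(synthetic_config(seed = 41))
  cp <- generate_corpus(w, 400, seed = 42)
  tgts <- lapply(cp$records, function(r) r$cod_sequence)
  v <- build_vocabulary(tgts)
  emitted <- sort(unique(unlist(tgts)))
  expect_setequal(setdiff(v$tokens, v$specials), emitted)
})

test_that("GEM mapping applies the first-listed candidate deterministically", {
  f <- withr::local_tempfile()
  writeLines(c("4280 I509 00000",
               "4281 I5020 10000",
               "4281 I5022 10000",
               "# comment"), f)
  gem <- read_gem_mapping(f)
  expect_equal(map_icd9_sequence("4280", gem), "I509")
  expect_equal(map_icd9_sequence("4281", gem), "I5020")  # first candidate
  expect_equal(gem_lookup(gem, "4281"), c("I5020", "I5022"))
  expect_null(gem_lookup(gem, "9999"))
  expect_warning(out <- map_icd9_sequence(c("4280", "9999"), gem), "9999")
  expect_equal(out, c("I509", "9999"))  # unmapped passes through
  expect_error(map_icd9_sequence("9999", gem, policy = "error"), "unmapped")
})

test_that("dataset splitting matches 7:1:2 and is a seeded partition", {
  pairs <- as.list(1:10)
  sp <- split_dataset(pairs, seed = 7)
  expect_equal(lengths(sp), c(train = 7L, val = 1L, test = 2L))
  sp2 <- split_dataset(pairs, seed = 7)
  expect_identical(sp, sp2)
  expect_setequal(unlist(sp), 1:10)

  pairs <- as.list(1:100)
  folds <- k_fold_split(pairs, k = 5, seed = 8)
  expect_equal(lengths(folds), rep(20L, 5))
  expect_setequal(unlist(folds), 1:100)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(unlist(folds[[i]]), unlist(folds[[j]])), 0)
  expect_error(k_fold_split(as.list(1:3), k = 5), "fewer pairs")
})
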