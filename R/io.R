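#' Read decedent records from CSV
#'
#' The carrier format is a plain CSV with header `id,diagnoses,cod_sequence`;
#' the two code lists are pipe-separated within their cells, e.g.
#' `d1,I251|I38|R000,I251|I469`. Codes are normalized on read. Records
#' violating the length bounds (45 diagnoses / 18 causes) are rejected with
#' an error naming the offending row numbers.
#'
#' @param path path to a decedent CSV file.
#' @return list of `decedent_record`, in file order.
#' @export
read_decedent_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("id", "diagnoses", "cod_sequence")
  if (!all(need %in% names(df)))
    stop("decedent CSV must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  bad_rows <- character(0)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    dx <- strsplit(df$diagnoses[i], "|", fixed = TRUE)[[1]]
    cod <- strsplit(df$cod_sequence[i], "|", fixed = TRUE)[[1]]
    dx <- dx[nzchar(dx)]
    cod <- cod[nzchar(cod)]
    if (length(dx) < 1 || length(dx) > 45 || length(cod) < 1 || length(cod) > 18) {
      bad_rows <- c(bad_rows, sprintf(
        "row %d (%d diagnoses, %d causes)", i, length(dx), length(cod)))
      next
    }
    records[[i]] <- decedent_record(df$id[i], dx, cod)
  }
  if (length(bad_rows) > 0)
    stop("invalid decedent record(s): ", paste(bad_rows, collapse = "; "),
         " [bounds: 1-45 diagnoses, 1-18 causes]")
  records
}

#' Write decedent records to CSV
#'
#' Inverse of [read_decedent_records()]; round trips are lossless on
#' normalized codes.
#'
#' @param records list of `decedent_record`.
#' @param path output path.
#' @export
write_decedent_records <- function(records, path) {
  df <- data.frame(
    id = vapply(records, function(r) r$record_id, character(1)),
    diagnoses = vapply(records, function(r) paste(r$diagnoses, collapse = "|"),
                       character(1)),
    cod_sequence = vapply(records, function(r) paste(r$cod_sequence, collapse = "|"),
                          character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a parallel token corpus
#'
#' Line i of the source file is the source code sequence of pair i joined by
#' single spaces; same for the target file. This mirrors the tokenized
#' text-file layout consumed by NMT training stacks.
#'
#' @param pairs list of `seq_pair`.
#' @param src_path,tgt_path output paths.
#' @export
write_parallel_corpus <- function(pairs, src_path, tgt_path) {
  src <- vapply(pairs, function(p) paste(p$source, collapse = " "), character(1))
  tgt <- vapply(pairs, function(p) paste(p$target, collapse = " "), character(1))
  writeLines(src, src_path)
  writeLines(tgt, tgt_path)
  invisible(c(src_path, tgt_path))
}

#' Read a parallel token corpus
#'
#' @param src_path,tgt_path paths to aligned source/target token files.
#' @return list of `seq_pair`.
#' @export
read_parallel_corpus <- function(src_path, tgt_path) {
  for (p in c(src_path, tgt_path)) if (!file.exists(p)) stop("no such file: ", p)
  src <- readLines(src_path)
  tgt <- readLines(tgt_path)
  if (length(src) != length(tgt))
    stop("line-count mismatch: ", length(src), " source lines vs ",
         length(tgt), " target lines")
  blank <- which(!nzchar(trimws(src)) | !nzchar(trimws(tgt)))
  if (length(blank) > 0)
    stop("blank corpus line(s) at: ", paste(blank, collapse = ", "))
  mapply(function(s, t) {
    seq_pair(strsplit(trimws(s), "[[:space:]]+")[[1]],
             strsplit(trimws(t), "[[:space:]]+")[[1]])
  }, src, tgt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Build a token vocabulary
#'
#' Four reserved specials occupy the lowest indices: `<pad>` (1), `<s>` (2),
#' `</s>` (3), `<unk>` (4). Remaining tokens are indexed by descending
#' corpus frequency, ties broken lexicographically, so indexing is stable
#' across runs for identical input.
#'
#' @param sequences list of character vectors (code sequences).
#' @param min_count minimum corpus frequency for inclusion (default 1).
#' @return a `vocabulary` object: fields `tokens` (index -> token),
#'   `index` (named integer, token -> index), `specials`.
#' @export
build_vocabulary <- function(sequences, min_count = 1) {
  if (min_count < 1) stop("min_count must be >= 1")
  if (length(sequences) == 0) stop("cannot build a vocabulary from an empty corpus")
  toks <- unlist(lapply(sequences, as.character), use.names = FALSE)
  if (length(toks) == 0) stop("cannot build a vocabulary from an empty corpus")
  tab <- table(toks)
  keep <- tab[tab >= min_count]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  kept <- names(keep)[ord]
  specials <- c("<pad>", "<s>", "</s>", "<unk>")
  tokens <- c(specials, kept)
  idx <- seq_along(tokens)
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx, specials = specials,
                 pad = 1L, sos = 2L, eos = 3L, unk = 4L),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$tokens) - 4L, " tokens + 4 specials\n", sep = "")
  invisible(x)
}

#' Map tokens to vocabulary indices
#'
#' Unknown tokens map to the `<unk>` index.
#'
#' @param vocab a `vocabulary`.
#' @param tokens character vector.
#' @return integer vector of indices.
#' @export
vocab_encode <- function(vocab, tokens) {
  i <- unname(vocab$index[tokens])
  i[is.na(i)] <- vocab$unk
  i
}

#' Map vocabulary indices back to tokens
#' @param vocab a `vocabulary`.
#' @param ids integer vector of indices.
#' @return character vector of tokens.
#' @export
vocab_decode <- function(vocab, ids) vocab$tokens[ids]

#' Write / read a vocabulary file (one token per line, index order)
#' @param vocab a `vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  specials <- c("<pad>", "<s>", "</s>", "<unk>")
  if (!identical(tokens[1:4], specials))
    stop("vocabulary file must start with the four specials <pad> <s> </s> <unk>")
  idx <- seq_along(tokens)
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx, specials = specials,
                 pad = 1L, sos = 2L, eos = 3L, unk = 4L),
            class = "vocabulary")
}

#' Read a GEM-style ICD-9 to ICD-10 mapping table
#'
#' Flat whitespace-separated text: columns `icd9 icd10 [flags...]`; flags
#' are ignored; repeated icd9 rows accumulate candidates in file order
#' (GEM files list preferred mappings first).
#'
#' @param path path to the mapping file.
#' @return a `gem_mapping`: environment keyed by ICD-9 code holding ordered
#'   character vectors of ICD-10 candidates.
#' @export
read_gem_mapping <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  env <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(f) < 2) stop("malformed GEM line ", i, ": ", lines[i])
    k <- normalize_icd(f[1])
    v <- normalize_icd(f[2])
    env[[k]] <- c(if (!is.null(env[[k]])) env[[k]], v)
  }
  structure(list(map = env), class = "gem_mapping")
}

#' Look up GEM candidates for one ICD-9 code
#'
#' @param gem a `gem_mapping`.
#' @param code one ICD-9 code.
#' @return character vector of candidates, or `NULL` if the code is unmapped
#'   (distinct from a code mapped to an empty set, which cannot occur).
#' @export
gem_lookup <- function(gem, code) {
  gem$map[[normalize_icd(code)]]
}

#' Map an ICD-9 code sequence to ICD-10
#'
#' Each code is replaced by its first-listed ICD-10 candidate. Under
#' `policy = "first"` unmapped codes pass through unchanged with a warning;
#' under `policy = "error"` any unmapped code raises. Output length always
#' equals input length.
#'
#' @param codes character vector of ICD-9 codes.
#' @param gem a `gem_mapping`.
#' @param policy `"first"` (default) or `"error"`.
#' @return character vector of ICD-10 (or passed-through) codes.
#' @export
map_icd9_sequence <- function(codes, gem, policy = c("first", "error")) {
  policy <- match.arg(policy)
  codes <- normalize_icd(codes)
  out <- character(length(codes))
  unmapped <- character(0)
  for (i in seq_along(codes)) {
    cand <- gem_lookup(gem, codes[i])
    if (is.null(cand)) {
      unmapped <- c(unmapped, codes[i])
      out[i] <- codes[i]
    } else {
      out[i] <- cand[1]
    }
  }
  if (length(unmapped) > 0) {
    if (policy == "error")
      stop("unmapped ICD-9 code(s): ", paste(unique(unmapped), collapse = ", "))
    warning("unmapped ICD-9 code(s) passed through: ",
            paste(unique(unmapped), collapse = ", "))
  }
  out
}

#' Split pairs into train/validation/test sets
#'
#' Sizes follow the requested ratios via largest-remainder rounding, so 10
#' pairs at 7:1:2 give exactly 7/1/2. The partition is exhaustive, disjoint
#' and reproducible from the seed.
#'
#' @param pairs list of pairs (any list).
#' @param ratios numeric length-3 vector of positive ratios summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed integer RNG seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(pairs, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three positive numbers summing to 1")
  n <- length(pairs)
  exact <- ratios * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  perm <- sample.int(n)
  i1 <- perm[seq_len(sizes[1])]
  i2 <- perm[sizes[1] + seq_len(sizes[2])]
  i3 <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  list(train = pairs[i1], val = pairs[i2], test = pairs[i3])
}

#' K-fold split
#'
#' @param pairs list of pairs.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return list of k disjoint folds whose union is the input.
#' @export
k_fold_split <- function(pairs, k = 5L, seed = 1L) {
  n <- length(pairs)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer pairs (", n, ") than folds (", k, ")")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  perm <- sample.int(n)
  fold_id <- rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
  unname(split(pairs[perm], fold_id))
}

# Save/restore .Random.seed around a locally seeded computation; returns a
# restore closure.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
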