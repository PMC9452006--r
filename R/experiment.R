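#' Experiment configuration
#'
#' One experiment is a cell of the five-experiment design: four
#' combinations of validity check x knowledge constraint on ICD-9 input,
#' plus ICD-10-mapped input with neither. The validity check applies to
#' training and validation corpora only, never to test data.
#'
#' @param coding `"icd9"` (native input) or `"icd10-mapped"` (sources
#'   passed through a GEM-style mapping first).
#' @param validity_check filter train/val pairs whose target chains contain
#'   an invalid adjacent pair.
#' @param knowledge_constraint constrain beam search to feasible
#'   successors.
#' @param model a [model_config()].
#' @param beam a [beam_config()] (`constrained` is set from
#'   `knowledge_constraint`).
#' @param split_seed seed for dataset splitting.
#' @param n_records synthetic corpus size for generated experiments.
#' @param n_folds folds for [cmd_experiment()].
#' @param paths named list: `output_dir` plus optional `corpus_csv`,
#'   `decision_table`, `gem_table`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(coding = c("icd9", "icd10-mapped"),
                              validity_check = FALSE,
                              knowledge_constraint = FALSE,
                              model = model_config(),
                              beam = beam_config(),
                              split_seed = 1L,
                              n_records = 2000L,
                              n_folds = 5L,
                              paths = list(output_dir = tempfile("mortseq_"))) {
  coding <- match.arg(coding)
  beam$constrained <- isTRUE(knowledge_constraint)
  structure(list(coding = coding,
                 validity_check = isTRUE(validity_check),
                 knowledge_constraint = isTRUE(knowledge_constraint),
                 model = model, beam = beam,
                 split_seed = as.integer(split_seed),
                 n_records = as.integer(n_records),
                 n_folds = as.integer(n_folds),
                 paths = paths),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Hierarchical keys mirror [experiment_config()]; `model:` and `beam:`
#' subtrees are passed to [model_config()] / [beam_config()].
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- do.call(model_config, if (is.null(y$model)) list() else y$model)
  bc <- do.call(beam_config, if (is.null(y$beam)) list() else y$beam)
  args <- y[setdiff(names(y), c("model", "beam"))]
  do.call(experiment_config, c(args, list(model = mc, beam = bc)))
}

.out_path <- function(config, ...) {
  dir.create(config$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$paths$output_dir, ...)
}

#' Write a knowledge graph as a decision-table file
#' @param graph a `knowledge_graph`.
#' @param path output path.
#' @export
write_decision_table <- function(graph, path) {
  e <- kg_edges(graph)
  writeLines(paste(e$cause, e$effect), path)
  invisible(path)
}

#' Generate a synthetic corpus experiment input
#'
#' Emits the decedent CSV, the ground-truth ledger and the decision table
#' of the planted causal graph into the output directory.
#'
#' @param config an `experiment_config`.
#' @param world_config optional [synthetic_config()]; defaults to the
#'   desk-scale preset seeded from the model seed.
#' @return invisible list of written paths plus the world.
#' @export
cmd_generate <- function(config, world_config = NULL) {
  if (is.null(world_config))
    world_config <- synthetic_config(seed = config$model$seed)
  world <- generate_world(world_config)
  corpus <- generate_corpus(world, config$n_records,
                            seed = config$split_seed)
  p_csv <- .out_path(config, "corpus.csv")
  p_led <- .out_path(config, "ledger.csv")
  p_dt <- .out_path(config, "decision_table.txt")
  write_decedent_records(corpus$records, p_csv)
  write_ledger(corpus$ledger, p_led)
  write_decision_table(world$graph, p_dt)
  invisible(list(corpus_csv = p_csv, ledger_csv = p_led,
                 decision_table = p_dt, world = world))
}

#' Preprocess: split, optionally validity-filter and GEM-map
#'
#' Reads the decedent CSV, converts to sequence pairs, optionally maps
#' ICD-9 sources to ICD-10 through the GEM table, splits 7:1:2, applies
#' the validity check to the training and validation sets only, and writes
#' the six corpus files plus vocabularies.
#'
#' @param config an `experiment_config`.
#' @return invisible list with the splits and the knowledge graph.
#' @export
cmd_preprocess <- function(config) {
  corpus_csv <- config$paths$corpus_csv %||% .out_path(config, "corpus.csv")
  records <- read_decedent_records(corpus_csv)
  pairs <- records_to_pairs(records)

  if (config$coding == "icd10-mapped") {
    gem <- read_gem_mapping(config$paths$gem_table)
    pairs <- lapply(pairs, function(p)
      seq_pair(map_icd9_sequence(p$source, gem), p$target))
  }

  dt_path <- config$paths$decision_table %||% .out_path(config, "decision_table.txt")
  universe <- sort(unique(unlist(lapply(pairs, function(p) p$target))))
  graph <- build_knowledge_graph(parse_decision_table(dt_path, universe),
                                 universe)

  sp <- split_dataset(pairs, seed = config$split_seed)
  filter_report <- NULL
  if (config$validity_check) {
    ftr <- validity_filter(sp$train, graph)
    fva <- validity_filter(sp$val, graph)
    sp$train <- ftr$kept
    sp$val <- fva$kept
    filter_report <- list(train = ftr$report, val = fva$report)
  }
  for (part in c("train", "val", "test")) {
    write_parallel_corpus(sp[[part]],
                          .out_path(config, paste0(part, ".src")),
                          .out_path(config, paste0(part, ".tgt")))
  }
  src_vocab <- build_vocabulary(lapply(sp$train, function(p) p$source))
  tgt_vocab <- build_vocabulary(lapply(sp$train, function(p) p$target))
  write_vocabulary(src_vocab, .out_path(config, "vocab.src"))
  write_vocabulary(tgt_vocab, .out_path(config, "vocab.tgt"))
  invisible(list(splits = sp, graph = graph, src_vocab = src_vocab,
                 tgt_vocab = tgt_vocab, filter_report = filter_report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a model on the preprocessed corpus
#'
#' @param config an `experiment_config`.
#' @return invisible trained model (also saved under the output directory
#'   with its training log).
#' @export
cmd_train <- function(config) {
  train <- read_parallel_corpus(.out_path(config, "train.src"),
                                .out_path(config, "train.tgt"))
  src_vocab <- read_vocabulary(.out_path(config, "vocab.src"))
  tgt_vocab <- read_vocabulary(.out_path(config, "vocab.tgt"))
  model <- train_model(train, src_vocab, tgt_vocab, config$model)
  save_model(model, .out_path(config, "model.rds"))
  write_training_log(model, .out_path(config, "train_log.tsv"))
  invisible(model)
}

#' Translate the test corpus
#'
#' @param config an `experiment_config`.
#' @param model optional model (defaults to the saved checkpoint).
#' @param graph optional knowledge graph (rebuilt from the decision table
#'   when the knowledge constraint is on).
#' @return invisible list of decode results; writes `test.out` and the
#'   score/attention sidecar.
#' @export
cmd_translate <- function(config, model = NULL, graph = NULL) {
  if (is.null(model)) model <- load_model(.out_path(config, "model.rds"))
  sources <- .read_token_file(.out_path(config, "test.src"))
  if (config$knowledge_constraint && is.null(graph)) {
    dt_path <- config$paths$decision_table %||% .out_path(config, "decision_table.txt")
    universe <- model$tgt_vocab$tokens[-(1:4)]
    graph <- build_knowledge_graph(parse_decision_table(dt_path, universe),
                                   universe)
  }
  results <- translate_sequences(model, sources, config$beam, graph)
  write_translations(results, .out_path(config, "test.out"),
                     .out_path(config, "test.scores.tsv"))
  invisible(results)
}

#' Evaluate translations against the test references
#'
#' @param config an `experiment_config`.
#' @return the `evaluation_report` (also written as JSON and text).
#' @export
cmd_evaluate <- function(config) {
  report <- evaluate_run(.out_path(config, "test.out"),
                         .out_path(config, "test.tgt"))
  write_evaluation_report(report,
                          json_path = .out_path(config, "evaluation.json"),
                          txt_path = .out_path(config, "evaluation.txt"))
  report
}

#' Run the full k-fold protocol for one experiment cell
#'
#' For each fold: train on the remaining folds (after optional validity
#' filtering), translate the held-out fold (optionally knowledge-
#' constrained) and evaluate; then aggregate mean (std) across folds.
#'
#' @param config an `experiment_config`.
#' @param pairs optional list of `seq_pair`; defaults to pairs from
#'   `paths$corpus_csv`.
#' @param graph optional `knowledge_graph`; defaults to the decision table
#'   in `paths`.
#' @return list with `folds` (per-fold `evaluation_report`s) and `summary`
#'   (the [cross_fold_report()] data frame).
#' @export
cmd_experiment <- function(config, pairs = NULL, graph = NULL) {
  if (is.null(pairs)) {
    records <- read_decedent_records(config$paths$corpus_csv %||%
                                       .out_path(config, "corpus.csv"))
    pairs <- records_to_pairs(records)
  }
  if (is.null(graph)) {
    dt_path <- config$paths$decision_table %||% .out_path(config, "decision_table.txt")
    universe <- sort(unique(unlist(lapply(pairs, function(p) p$target))))
    graph <- build_knowledge_graph(parse_decision_table(dt_path, universe),
                                   universe)
  }
  folds <- k_fold_split(pairs, k = config$n_folds, seed = config$split_seed)
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- unlist(folds[-f], recursive = FALSE)
    if (config$validity_check) train <- validity_filter(train, graph)$kept
    src_vocab <- build_vocabulary(lapply(train, function(p) p$source))
    tgt_vocab <- build_vocabulary(lapply(train, function(p) p$target))
    model <- train_model(train, src_vocab, tgt_vocab, config$model)
    results <- translate_sequences(model, lapply(test, function(p) p$source),
                                   config$beam,
                                   if (config$knowledge_constraint) graph)
    reports[[f]] <- evaluate_run(lapply(results, function(r) r$tokens),
                                 lapply(test, function(p) p$target))
  }
  summary <- cross_fold_report(reports)
  utils::write.table(summary, .out_path(config, "experiment_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(folds = reports, summary = summary)
}
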