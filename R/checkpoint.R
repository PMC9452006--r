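#' Save a model checkpoint
#'
#' Single-file archive (RDS) containing a versioned magic header, the
#' configuration, both vocabularies and all parameters. A save/load round
#' trip preserves every output bit for bit.
#'
#' @param model a `seq2seq_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  payload <- list(
    magic = "mortseq-checkpoint",
    version = 1L,
    config = model$config,
    src_vocab = model$src_vocab,
    tgt_vocab = model$tgt_vocab,
    params = lapply(model$params, function(p) p$val),
    log = model$log,
    final_loss = model$final_loss
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$magic, "mortseq-checkpoint"))
    stop("not a mortseq checkpoint: ", path)
  if (payload$version > 1L)
    stop("checkpoint version ", payload$version, " is newer than supported")
  model <- new_model(payload$config, payload$src_vocab, payload$tgt_vocab)
  if (!identical(sort(names(model$params)), sort(names(payload$params))))
    stop("checkpoint parameter set does not match the configuration")
  for (nm in names(payload$params)) model$params[[nm]]$val <- payload$params[[nm]]
  model$log <- payload$log
  model$final_loss <- payload$final_loss
  model
}

#' Write a training log as TSV
#' @param model a trained `seq2seq_model`.
#' @param path TSV path.
#' @export
write_training_log <- function(model, path) {
  utils::write.table(model$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
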