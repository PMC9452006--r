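#' Configuration for the synthetic mortality world
#'
#' Defaults reproduce the published shape of a large US state vital
#' statistics extract: a mean of 18.84 discharge diagnosis codes and 2.25
#' cause-of-death codes per decedent, with 31.77% single-code cause
#' sequences. Vocabulary sizes default to a desk-scale 400 source / 150
#' target codes; `scale = "full"` switches to the full-scale 7,616 / 2,649.
#'
#' @param n_source_codes,n_target_codes vocabulary sizes (>= 4).
#' @param mean_diagnoses mean number of diagnosis codes per record.
#' @param mean_cod_length mean cause-of-death chain length.
#' @param single_code_target_fraction probability of a single-code chain.
#' @param edge_density directed-edge density of the planted causal graph.
#' @param noise_code_fraction fraction of each diagnosis list reserved for
#'   non-informative noise codes.
#' @param invalid_pair_plant_rate probability that a multi-code chain gets
#'   one adjacent pair rewired to a non-edge (and the record flagged).
#' @param seed integer seed for world generation.
#' @param scale `"desk"` (default) or `"full"` vocabulary preset; explicit
#'   vocabulary arguments override it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_source_codes = NULL,
                             n_target_codes = NULL,
                             mean_diagnoses = 18.84,
                             mean_cod_length = 2.25,
                             single_code_target_fraction = 0.3177,
                             edge_density = 0.05,
                             noise_code_fraction = 0.25,
                             invalid_pair_plant_rate = 0,
                             seed = 1L,
                             scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(n_source_codes))
    n_source_codes <- if (scale == "full") 7616L else 400L
  if (is.null(n_target_codes))
    n_target_codes <- if (scale == "full") 2649L else 150L
  cfg <- list(n_source_codes = as.integer(n_source_codes),
              n_target_codes = as.integer(n_target_codes),
              mean_diagnoses = mean_diagnoses,
              mean_cod_length = mean_cod_length,
              single_code_target_fraction = single_code_target_fraction,
              edge_density = edge_density,
              noise_code_fraction = noise_code_fraction,
              invalid_pair_plant_rate = invalid_pair_plant_rate,
              seed = as.integer(seed))
  fr <- c(cfg$single_code_target_fraction, cfg$edge_density,
          cfg$noise_code_fraction, cfg$invalid_pair_plant_rate)
  if (any(fr < 0) || any(fr > 1)) stop("all fractions must lie in [0,1]")
  if (cfg$mean_diagnoses < 1 || cfg$mean_cod_length < 1)
    stop("mean lengths must be >= 1")
  if (cfg$n_source_codes < 4 || cfg$n_target_codes < 4)
    stop("vocabulary sizes must be >= 4")
  structure(cfg, class = "synthetic_config")
}

# Synthetic code labels: source codes mimic ICD-9 numerics, target codes
# ICD-10 letter+digits. Zero-padded so lexicographic order is stable.
.src_code_labels <- function(n) sprintf("D%05d", seq_len(n))
.tgt_code_labels <- function(n) sprintf("C%04d", seq_len(n))

#' Generate a synthetic mortality world
#'
#' Builds, deterministically from the config seed: a directed causal graph
#' over the target codes (no self loops) at the configured edge density,
#' with every code guaranteed at least one successor when chains longer
#' than one code are requested; and an evidence map assigning each target
#' code 3-8 characteristic source codes, which is what makes the
#' translation task learnable.
#'
#' @param config a `synthetic_config`.
#' @return a `synthetic_world`: source/target code vectors, the causal
#'   `knowledge_graph`, the evidence map, and the config.
#' @export
generate_world <- function(config) {
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)

  tgt <- .tgt_code_labels(config$n_target_codes)
  src <- .src_code_labels(config$n_source_codes)
  nt <- length(tgt)

  need_chains <- config$mean_cod_length > 1 ||
    config$single_code_target_fraction < 1
  if (config$edge_density <= 0 && need_chains)
    stop("edge_density 0 is incompatible with multi-code chains ",
         "(no node can have a successor)")

  # Directed Erdos-Renyi adjacency over target codes, no self loops.
  adj <- new.env(parent = emptyenv())
  n_edges <- 0L
  for (i in seq_len(nt)) {
    out <- which(stats::runif(nt) < config$edge_density)
    out <- out[out != i]
    if (length(out) == 0 && need_chains) {
      out <- sample(seq_len(nt)[-i], 1L)  # guarantee out-degree >= 1
    }
    if (length(out) > 0) {
      adj[[tgt[i]]] <- sort(tgt[out], method = "radix")
      n_edges <- n_edges + length(out)
    }
  }
  graph <- structure(list(adj = adj, n_edges = n_edges),
                     class = "knowledge_graph")

  # Evidence map: each target code -> 3-8 characteristic source codes.
  evidence <- lapply(seq_len(nt), function(i) {
    sample(src, sample(3:8, 1L))
  })
  names(evidence) <- tgt

  chain_starts <- tgt[vapply(tgt, function(c) !is.null(adj[[c]]), logical(1))]

  structure(list(source_codes = src, target_codes = tgt, graph = graph,
                 evidence = evidence, chain_starts = chain_starts,
                 chain_lambda = .chain_length_lambda(config),
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", length(x$source_codes), " source codes, ",
      length(x$target_codes), " target codes, ",
      x$graph$n_edges, " causal edges\n", sep = "")
  invisible(x)
}

# Multi-code chains have length max(1 + Poisson(lambda), 2); lambda is
# calibrated numerically so the unconditional chain-length mean equals
# mean_cod_length given the single-code fraction:
#   f + (1 - f) * (1 + lambda + exp(-lambda)) = mean_cod_length
.chain_length_lambda <- function(config) {
  f <- config$single_code_target_fraction
  if (f >= 1) return(0)
  target <- (config$mean_cod_length - 1) / (1 - f)  # = lambda + exp(-lambda)
  if (target <= 1) return(0)
  stats::uniroot(function(l) l + exp(-l) - target,
                 lower = 0, upper = max(target, 1) + 1)$root
}

#' Sample one synthetic decedent record
#'
#' The cause-of-death chain is a random walk along the planted causal graph
#' (underlying cause first); with probability
#' `single_code_target_fraction` it is a single code. Diagnoses are the
#' characteristic evidence codes of each chain code, in chain order
#' (emulating priority-ordered discharge codes), followed by noise codes,
#' truncated/padded to a Poisson(mean_diagnoses) length clipped to [1,45].
#' With probability `invalid_pair_plant_rate` one adjacent chain pair of a
#' multi-code chain is rewired to a non-edge and the record is flagged.
#'
#' @param world a `synthetic_world`.
#' @param id record identifier.
#' @return list: `record` (a `decedent_record`), `truth` (chain before any
#'   planting, planted flag, evidence/noise split of the diagnoses).
#' @export
sample_decedent <- function(world, id = "r1") {
  cfg <- world$config
  tgt <- world$target_codes

  # chain
  if (stats::runif(1) < cfg$single_code_target_fraction) {
    chain <- sample(tgt, 1L)
  } else {
    len <- min(1L + stats::rpois(1, world$chain_lambda), 18L)
    len <- max(len, 2L)
    chain <- sample(world$chain_starts, 1L)
    while (length(chain) < len) {
      succ <- world$graph$adj[[chain[length(chain)]]]
      if (is.null(succ)) break
      chain <- c(chain, if (length(succ) == 1L) succ else sample(succ, 1L))
    }
  }
  true_chain <- chain

  # optional invalid-adjacency planting (multi-code chains only)
  planted <- FALSE
  if (length(chain) >= 2 && stats::runif(1) < cfg$invalid_pair_plant_rate) {
    pos <- if (length(chain) == 2L) 1L else sample(length(chain) - 1L, 1L)
    non_succ <- setdiff(tgt, c(world$graph$adj[[chain[pos]]], chain[pos]))
    if (length(non_succ) > 0) {
      chain[pos + 1L] <- if (length(non_succ) == 1L) non_succ else sample(non_succ, 1L)
      planted <- TRUE
    }
  }

  # diagnoses: evidence in chain order, then noise, length ~ Poisson clipped
  d_len <- min(max(stats::rpois(1, cfg$mean_diagnoses), 1L), 45L)
  evid <- unique(unlist(world$evidence[true_chain], use.names = FALSE))
  n_keep_evid <- min(length(evid), d_len)
  n_noise <- d_len - n_keep_evid
  noise <- if (n_noise > 0) sample(world$source_codes, n_noise, replace = TRUE)
           else character(0)
  diagnoses <- c(evid[seq_len(n_keep_evid)], noise)

  list(
    record = decedent_record(id, diagnoses, chain),
    truth = list(true_chain = true_chain, planted = planted,
                 evidence_codes = evid[seq_len(n_keep_evid)],
                 noise_codes = noise)
  )
}

#' Generate a synthetic corpus with a ground-truth ledger
#'
#' @param world a `synthetic_world`.
#' @param n number of records (>= 1).
#' @param seed integer seed for sampling.
#' @return list: `records` (list of `decedent_record`) and `ledger` (data
#'   frame: id, planted flag, true chain as a pipe-joined string).
#' @export
generate_corpus <- function(world, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  records <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_decedent(world, id = sprintf("r%06d", i))
    records[[i]] <- s$record
    truths[[i]] <- s$truth
  }
  ledger <- data.frame(
    id = vapply(records, function(r) r$record_id, character(1)),
    planted_invalid = vapply(truths, function(t) t$planted, logical(1)),
    true_chain = vapply(truths, function(t) paste(t$true_chain, collapse = "|"),
                        character(1)),
    n_evidence = vapply(truths, function(t) length(t$evidence_codes), integer(1)),
    stringsAsFactors = FALSE
  )
  list(records = records, ledger = ledger, truths = truths)
}

#' Write a ground-truth ledger as CSV
#' @param ledger data frame from [generate_corpus()].
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
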