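#' Parse an ACME-style decision table
#'
#' The decision table is a plain-text ontology of medically valid causal
#' relationships between ICD-10 codes. Each non-comment line holds either
#' two codes, `F2 F3`, read as "cause F2 may lead to effect F3", or three
#' codes, `F1 F2 F3`, read as a range rule: every code in the closed
#' interval `F1..F2` (in the ordering induced by `code_universe`) may lead
#' to F3.
#'
#' @param path path to the decision-table file. Lines starting with `#` are
#'   ignored.
#' @param code_universe ordered character vector of codes supplying the
#'   total ordering used for range expansion (typically the sorted target
#'   vocabulary).
#' @return data frame of rules with columns `cause_low`, `cause_high`,
#'   `effect`.
#' @export
parse_decision_table <- function(path, code_universe) {
  if (!file.exists(path)) stop("no such file: ", path)
  code_universe <- normalize_icd(code_universe)
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  bad <- character(0)
  rules <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (!(length(f) %in% c(2L, 3L))) {
      bad <- c(bad, sprintf("line %d (%d tokens)", i, length(f)))
      next
    }
    f <- normalize_icd(f)
    if (length(f) == 2L) {
      rules[[length(rules) + 1L]] <- c(f[1], f[1], f[2])
    } else {
      if (f[1] > f[2])
        bad <- c(bad, sprintf("line %d (range %s > %s)", i, f[1], f[2]))
      else
        rules[[length(rules) + 1L]] <- f
    }
  }
  if (length(bad) > 0)
    stop("malformed decision-table line(s): ", paste(bad, collapse = "; "))
  m <- do.call(rbind, rules)
  if (is.null(m)) m <- matrix(character(0), ncol = 3)
  data.frame(cause_low = m[, 1], cause_high = m[, 2], effect = m[, 3],
             stringsAsFactors = FALSE)
}

#' Build a causal knowledge graph from rules
#'
#' Nodes are ICD codes; a directed edge (cause, effect) is present iff some
#' rule covers it after range expansion over `code_universe`. The graph is
#' stored as a hash-map adjacency (cause -> sorted vector of effects), which
#' is what constrained decoding and the validity filter query.
#'
#' @param rules data frame from [parse_decision_table()], or any data frame
#'   with columns `cause_low`, `cause_high`, `effect`.
#' @param code_universe ordered character vector used for range expansion.
#' @return a `knowledge_graph` object.
#' @export
build_knowledge_graph <- function(rules, code_universe) {
  code_universe <- sort(normalize_icd(code_universe), method = "radix")
  adj <- new.env(parent = emptyenv())
  n_edges <- 0L
  if (nrow(rules) > 0) {
    for (i in seq_len(nrow(rules))) {
      lo <- rules$cause_low[i]; hi <- rules$cause_high[i]; eff <- rules$effect[i]
      causes <- if (lo == hi) lo
        else code_universe[code_universe >= lo & code_universe <= hi]
      for (c in causes) {
        cur <- adj[[c]]
        if (is.null(cur) || !(eff %in% cur)) {
          adj[[c]] <- c(cur, eff)
          n_edges <- n_edges + 1L
        }
      }
    }
  }
  # canonical order for reproducible successor sets
  for (c in ls(adj)) adj[[c]] <- sort(adj[[c]], method = "radix")
  structure(list(adj = adj, n_edges = n_edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> ", length(ls(x$adj)), " cause nodes, ",
      x$n_edges, " directed edges\n", sep = "")
  invisible(x)
}

#' List all edges of a knowledge graph
#' @param graph a `knowledge_graph`.
#' @return data frame with columns `cause`, `effect` (useful e.g. for
#'   igraph conversion).
#' @export
kg_edges <- function(graph) {
  causes <- sort(ls(graph$adj), method = "radix")
  if (length(causes) == 0)
    return(data.frame(cause = character(0), effect = character(0)))
  eff <- lapply(causes, function(c) graph$adj[[c]])
  data.frame(cause = rep(causes, lengths(eff)),
             effect = unlist(eff, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Is (cause, effect) a medically valid ordered pair?
#'
#' @param graph a `knowledge_graph`.
#' @param cause,effect single ICD codes.
#' @return `TRUE` iff the directed edge is present; codes absent from the
#'   graph yield `FALSE`.
#' @export
is_valid_pair <- function(graph, cause, effect) {
  succ <- graph$adj[[normalize_icd(cause)]]
  !is.null(succ) && normalize_icd(effect) %in% succ
}

#' Medically feasible successors of a code
#'
#' @param graph a `knowledge_graph`.
#' @param code a single ICD code.
#' @return character vector of effect codes (empty if the code is unknown).
#' @export
allowed_successors <- function(graph, code) {
  succ <- graph$adj[[normalize_icd(code)]]
  if (is.null(succ)) character(0) else succ
}

#' Validity-check corpus filter
#'
#' Removes a sequence pair iff its target sequence has length >= 2 and any
#' adjacent code pair (y_i, y_{i+1}) is not a valid causal edge. Single-code
#' targets are always kept (there is no pair to validate). The filter is
#' idempotent. Intended for training and validation corpora; test data is
#' conventionally left unfiltered.
#'
#' @param pairs list of `seq_pair`.
#' @param graph a `knowledge_graph`.
#' @return list with `kept`, `removed` (both lists of pairs), and `report`
#'   (n_input, n_kept, n_removed, removal_rate, removed_idx).
#' @export
validity_filter <- function(pairs, graph) {
  valid <- vapply(pairs, function(p) target_chain_valid(p$target, graph),
                  logical(1))
  removed_idx <- which(!valid)
  list(
    kept = pairs[valid],
    removed = pairs[!valid],
    report = list(
      n_input = length(pairs),
      n_kept = sum(valid),
      n_removed = length(removed_idx),
      removal_rate = if (length(pairs) > 0) length(removed_idx) / length(pairs) else 0,
      removed_idx = removed_idx
    )
  )
}

#' Are all adjacent pairs of a target chain valid edges?
#' @param target character vector of codes.
#' @param graph a `knowledge_graph`.
#' @return logical scalar; `TRUE` for single-code chains.
#' @export
target_chain_valid <- function(target, graph) {
  n <- length(target)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    if (!is_valid_pair(graph, target[i], target[i + 1])) return(FALSE)
  }
  TRUE
}
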