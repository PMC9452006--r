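#' Extract the output-by-input attention matrix for a decoded record
#'
#' Force-decodes `generated` against `source`, collecting the attention
#' weight vector at each output step: one row per generated cause-of-death
#' code (underlying cause first), one column per input diagnosis code in
#' source order. Rows are softmax-normalized by construction.
#'
#' @param model a `seq2seq_model`.
#' @param source character vector of input diagnosis codes.
#' @param generated character vector of generated (or reference) cause
#'   codes.
#' @return labeled attention matrix (`length(generated)` x
#'   `length(source)`).
#' @export
extract_attention <- function(model, source, generated) {
  source <- normalize_icd(source)
  generated <- normalize_icd(generated)
  state <- ms_encode(model, source)
  prev <- "<s>"
  rows <- vector("list", length(generated))
  for (t in seq_along(generated)) {
    st <- ms_step(model, state, prev)
    rows[[t]] <- st$attn
    state <- st$state
    prev <- generated[t]
  }
  A <- do.call(rbind, rows)
  if (ncol(A) != length(source))
    stop("attention width ", ncol(A), " does not match source length ",
         length(source))
  dimnames(A) <- list(generated, source)
  A
}

#' Identify death-related conditions by attention thresholding
#'
#' An input diagnosis code is flagged as death-related iff its maximum
#' attention weight over all output rows reaches the threshold (inclusive).
#' The default threshold of 0.1 follows the case-study convention; raising
#' it never grows the related set.
#'
#' @param matrix labeled attention matrix from [extract_attention()] (or a
#'   decode result's `attention`).
#' @param threshold relatedness cutoff in (0, 1); default 0.1.
#' @return a `death_related_report`: `threshold`, `related` (data frame of
#'   input position, code and max attention, in source order), `unrelated`
#'   (the remaining codes, source order).
#' @export
death_related_conditions <- function(matrix, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  if (nrow(matrix) < 1 || ncol(matrix) < 1) stop("empty attention matrix")
  max_att <- apply(matrix, 2L, max)
  codes <- colnames(matrix)
  if (is.null(codes)) codes <- paste0("pos", seq_len(ncol(matrix)))
  rel <- max_att >= threshold
  structure(list(
    threshold = threshold,
    related = data.frame(position = which(rel), code = codes[rel],
                         max_attention = unname(max_att[rel]),
                         row.names = NULL, stringsAsFactors = FALSE),
    unrelated = data.frame(position = which(!rel), code = codes[!rel],
                           max_attention = unname(max_att[!rel]),
                           row.names = NULL, stringsAsFactors = FALSE)
  ), class = "death_related_report")
}

#' @export
print.death_related_report <- function(x, ...) {
  cat("<death_related_report> threshold ", x$threshold, ": ",
      nrow(x$related), " related / ",
      nrow(x$related) + nrow(x$unrelated), " input codes\n", sep = "")
  if (nrow(x$related) > 0) {
    for (i in seq_len(nrow(x$related)))
      cat(sprintf("  %-8s max attention %.3f\n",
                  x$related$code[i], x$related$max_attention[i]))
  }
  invisible(x)
}

#' Export an attention matrix as TSV (and optionally a PNG heatmap)
#'
#' The TSV (labeled, readable back with [read_heatmap_tsv()]) is the
#' contract; the image is best-effort.
#'
#' @param matrix labeled attention matrix.
#' @param path TSV output path.
#' @param png_path optional heatmap image path.
#' @export
export_heatmap <- function(matrix, path, png_path = NULL) {
  if (nrow(matrix) < 1 || ncol(matrix) < 1) stop("empty attention matrix")
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(png_path)) {
    tryCatch({
      grDevices::png(png_path, width = 640, height = 480)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::image(
        x = seq_len(ncol(matrix)), y = seq_len(nrow(matrix)),
        z = t(matrix[rev(seq_len(nrow(matrix))), , drop = FALSE]),
        col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
        xlab = "input diagnosis codes", ylab = "causes of death",
        axes = FALSE)
      graphics::axis(1, seq_len(ncol(matrix)), colnames(matrix), las = 2)
      graphics::axis(2, seq_len(nrow(matrix)), rev(rownames(matrix)), las = 1)
    }, error = function(e) invisible(NULL))
  }
  invisible(path)
}

#' @rdname export_heatmap
#' @export
read_heatmap_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
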