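#' Normalize ICD code tokens
#'
#' ICD-9 and ICD-10 codes appear in the wild both with and without the
#' decimal point ("J44.9" vs "J449") and in mixed case. All code ingress in
#' this package funnels through this function, which strips dots and
#' whitespace and uppercases, so that "j44.9", "J44.9" and "J449" are the
#' same token everywhere downstream.
#'
#' @param x character vector of raw code tokens.
#' @return character vector of normalized tokens.
#' @examples
#' normalize_icd("J44.9")  # "J449"
#' @export
normalize_icd <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- toupper(gsub("[.[:space:]]", "", x))
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop("empty ICD code token(s) after normalization at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  out
}

#' Construct a code sequence
#'
#' A code sequence is an ordered character vector of normalized ICD codes;
#' order is significant (position 1 of a cause-of-death sequence is the
#' underlying cause of death).
#'
#' @param codes character vector of at least one code.
#' @return normalized character vector with class `code_seq`.
#' @export
code_seq <- function(codes) {
  if (length(codes) < 1) stop("a code sequence must contain at least one code")
  structure(normalize_icd(codes), class = "code_seq")
}

#' @export
print.code_seq <- function(x, ...) {
  cat("<code_seq> ", paste(unclass(x), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Construct a decedent record
#'
#' One record per decedent: up to 45 priority-ordered discharge diagnosis
#' codes and a cause-of-death sequence of 1 underlying cause plus up to 17
#' related causes, underlying cause first.
#'
#' @param record_id scalar identifier.
#' @param diagnoses character vector of 1-45 diagnosis codes.
#' @param cod_sequence character vector of 1-18 cause-of-death codes.
#' @return a list with class `decedent_record`.
#' @export
decedent_record <- function(record_id, diagnoses, cod_sequence) {
  diagnoses <- normalize_icd(diagnoses)
  cod_sequence <- normalize_icd(cod_sequence)
  if (length(diagnoses) < 1 || length(diagnoses) > 45)
    stop("diagnoses must contain 1-45 codes (got ", length(diagnoses), ")")
  if (length(cod_sequence) < 1 || length(cod_sequence) > 18)
    stop("cod_sequence must contain 1-18 codes (got ", length(cod_sequence), ")")
  structure(
    list(record_id = as.character(record_id),
         diagnoses = diagnoses,
         cod_sequence = cod_sequence),
    class = "decedent_record"
  )
}

#' @export
print.decedent_record <- function(x, ...) {
  cat("<decedent_record> id=", x$record_id,
      " | ", length(x$diagnoses), " diagnoses | underlying COD ",
      x$cod_sequence[1],
      if (length(x$cod_sequence) > 1)
        paste0(" (+", length(x$cod_sequence) - 1, " related)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Construct a source/target sequence pair
#'
#' @param source character vector of source (diagnosis) codes.
#' @param target character vector of target (cause-of-death) codes.
#' @return list with class `seq_pair`.
#' @export
seq_pair <- function(source, target) {
  if (length(source) < 1 || length(target) < 1)
    stop("both sides of a sequence pair must be non-empty")
  structure(list(source = normalize_icd(source),
                 target = normalize_icd(target)),
            class = "seq_pair")
}

#' Convert decedent records to sequence pairs
#'
#' @param records list of `decedent_record`.
#' @return list of `seq_pair` (diagnoses -> cod_sequence).
#' @export
records_to_pairs <- function(records) {
  lapply(records, function(r) seq_pair(r$diagnoses, r$cod_sequence))
}
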