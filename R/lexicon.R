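#' Load a phenotype lexicon
#'
#' The lexicon is the dictionary behind the default concept recognizer: a TSV
#' mapping surface terms to SNOMED-CT codes and preferred labels. Terms are
#' normalized by case-folding and whitespace squashing; two different terms
#' normalizing to the same string must agree on the code, otherwise loading
#' fails.
#'
#' @param path Two-or-three-column TSV (`term`, `code`, optional `label`).
#'   Defaults to the mini-lexicon shipped with the package.
#' @return Object of class `phenotype_lexicon`.
#' @export
load_lexicon <- function(path = system.file(
    "extdata", "phenotype_lexicon.tsv", package = "phenossu",
    mustWork = TRUE)) {
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    entries <- data.frame(term = character(), norm = character(),
                          code = character(), label = character(),
                          stringsAsFactors = FALSE)
    return(structure(list(entries = entries), class = "phenotype_lexicon"))
  }
  if (!all(c("term", "code") %in% names(raw))) {
    stop("lexicon must have columns 'term' and 'code'")
  }
  if (is.null(raw$label)) raw$label <- raw$term
  raw$label <- ifelse(nzchar(raw$label), raw$label, raw$term)
  norm <- normalize_term(raw$term)
  if (any(!nzchar(norm))) stop("lexicon contains an empty term")
  split_codes <- split(raw$code, norm)
  conflict <- names(split_codes)[vapply(split_codes, function(cd)
    length(unique(cd)) > 1L, NA)]
  if (length(conflict)) {
    stop("conflicting codes for normalized lexicon term(s): ",
         paste(conflict, collapse = ", "))
  }
  keep <- !duplicated(norm)
  entries <- data.frame(term = raw$term[keep], norm = norm[keep],
                        code = raw$code[keep], label = raw$label[keep],
                        stringsAsFactors = FALSE)
  structure(list(entries = entries), class = "phenotype_lexicon")
}

normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

lexicon_lookup <- function(lexicon, surface) {
  stopifnot(inherits(lexicon, "phenotype_lexicon"))
  i <- match(normalize_term(surface), lexicon$entries$norm)
  if (is.na(i)) return(NULL)
  as.list(lexicon$entries[i, ])
}

#' @export
print.phenotype_lexicon <- function(x, ...) {
  cat(sprintf("<phenotype_lexicon: %d terms, %d concepts>\n",
              nrow(x$entries), length(unique(x$entries$code))))
  invisible(x)
}

#' Recognize phenotype concept mentions in text
#'
#' Dictionary matching: case-insensitive, whole-token, longest-match-first and
#' non-overlapping. Deterministic, and invariant to trailing whitespace.
#'
#' @param text Document text.
#' @param lexicon A `phenotype_lexicon`.
#' @return List of [phenotype_concept()] objects sorted by span start.
#' @export
recognize <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "phenotype_lexicon"))
  hits <- match_terms(text, lexicon$entries$term)
  lapply(seq_len(nrow(hits)), function(i) {
    entry <- lexicon_lookup(lexicon, hits$term[i])
    phenotype_concept(hits$text[i], hits$start[i], hits$end[i],
                      entry$code, entry$label, doc_text = text)
  })
}

#' Ingest phenotype spans produced by an external recognizer
#'
#' Adapter for plugging in the output of any external concept recognizer:
#' records are validated against the document and converted to
#' [phenotype_concept()] objects. Out-of-bound or inverted spans are dropped
#' individually with a warning.
#'
#' @param records data.frame with columns `start`, `end` (0-based,
#'   end-exclusive) and `code`; an optional `label` column is carried through.
#' @param doc_text The document the spans refer to.
#' @return List of validated `phenotype_concept` objects.
#' @export
ingest_external_spans <- function(records, doc_text) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(list())
  n <- nchar(doc_text)
  ok <- !is.na(records$start) & !is.na(records$end) &
    records$start >= 0L & records$end <= n & records$start < records$end
  if (any(!ok)) {
    warning(sum(!ok), " external span record(s) out of bounds; dropped")
  }
  if (!any(ok)) stop("all external span records are invalid")
  records <- records[ok, , drop = FALSE]
  lapply(seq_len(nrow(records)), function(i) {
    surface <- span_text(doc_text, records$start[i], records$end[i])
    phenotype_concept(surface, records$start[i], records$end[i],
                      records$code[i],
                      if (!is.null(records$label)) records$label[i]
                      else surface,
                      doc_text = doc_text)
  })
}
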