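#' Split text into sentences
#'
#' Rule-based splitting on `.`, `!` or `?` followed by whitespace or end of
#' text, with a stop-list of common abbreviations that do not end sentences.
#' Sentence intervals tile the text in order (whitespace between sentences
#' belongs to no sentence).
#'
#' @param text Document text.
#' @return data.frame with columns `sentence`, `start`, `end` (0-based,
#'   end-exclusive offsets into `text`).
#' @export
split_sentences <- function(text) {
  empty <- data.frame(sentence = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(trimws(text))) return(empty)
  abbrev <- c("e.g", "i.e", "etc", "vs", "cf", "dr", "mr", "mrs", "fig",
              "no", "st", "approx")
  m <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  bounds <- integer()
  if (m[1] != -1L) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      endpos <- as.integer(m[i]) + len[i] - 1L  # 1-based last punct char
      # token immediately before the punctuation, including its own dots
      pre <- sub(".*?([[:alnum:].]*)$",
                 "\\1", substr(text, 1L, as.integer(m[i]) - 1L))
      if (tolower(sub("\\.+$", "", pre)) %in% abbrev) next
      bounds <- c(bounds, endpos)
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  out <- list()
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    chunk <- substr(text, starts[i], ends[i])
    lead <- nchar(chunk) - nchar(sub("^[[:space:]]+", "", chunk))
    trail <- nchar(chunk) - nchar(sub("[[:space:]]+$", "", chunk))
    s <- starts[i] + lead
    e <- ends[i] - trail
    if (s > e) next
    out[[length(out) + 1L]] <- data.frame(
      sentence = substr(text, s, e), start = s - 1L, end = e,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Find attribute-value trigger mentions in a sentence
#'
#' Exact string matching of the schema's trigger lexicons: case-insensitive,
#' whole-word, longest-match-first; matches for the same attribute never
#' overlap (triggers of different attributes may).
#'
#' @param sentence One sentence of text.
#' @param schema A `phenossu_schema` providing per-value trigger terms.
#' @return data.frame with columns `attribute`, `value`, `trigger`, `start`,
#'   `end` (offsets within `sentence`).
#' @export
find_trigger_mentions <- function(sentence, schema) {
  stopifnot(inherits(schema, "phenossu_schema"))
  cat_tab <- trigger_catalog(schema)
  out <- list()
  for (attr_name in unique(cat_tab$attribute)) {
    sub_tab <- cat_tab[cat_tab$attribute == attr_name, , drop = FALSE]
    hits <- match_terms(sentence, sub_tab$trigger)
    if (nrow(hits) == 0L) next
    i <- match(tolower(hits$term), tolower(sub_tab$trigger))
    out[[length(out) + 1L]] <- data.frame(
      attribute = attr_name, value = sub_tab$value[i], trigger = hits$term,
      start = hits$start, end = hits$end, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(attribute = character(), value = character(),
                      trigger = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$attribute), , drop = FALSE]
}

#' Build the sentence-level co-occurrence table
#'
#' The schema-design procedure: a sentence contributes to attribute `a` iff it
#' contains at least one phenotype mention and at least one trigger of any
#' value of `a`. Counts are numbers of distinct sentences per attribute.
#'
#' @param corpus Named character vector (or list) of document texts.
#' @param lexicon A `phenotype_lexicon` for phenotype mentions.
#' @param schema A `phenossu_schema` providing trigger lexicons.
#' @return Object of class `cooccurrence_table`: per attribute the set of
#'   sentence ids (`doc#index`) and an example sentence, with a `counts`
#'   accessor via [cooccurrence_counts()].
#' @export
build_cooccurrence_table <- function(corpus, lexicon, schema) {
  if (is.null(names(corpus))) {
    names(corpus) <- sprintf("doc%03d", seq_along(corpus))
  }
  attrs <- attribute_names(schema)
  sets <- stats::setNames(rep(list(character()), length(attrs)), attrs)
  examples <- stats::setNames(rep(NA_character_, length(attrs)), attrs)
  for (doc_id in names(corpus)) {
    sents <- split_sentences(corpus[[doc_id]])
    for (i in seq_len(nrow(sents))) {
      sent <- sents$sentence[i]
      if (nrow(match_terms(sent, lexicon$entries$term)) == 0L) next
      trig <- find_trigger_mentions(sent, schema)
      if (nrow(trig) == 0L) next
      sid <- paste0(doc_id, "#", i)
      for (a in unique(trig$attribute)) {
        sets[[a]] <- union(sets[[a]], sid)
        if (is.na(examples[[a]])) examples[[a]] <- sent
      }
    }
  }
  structure(list(sentence_sets = sets, examples = examples),
            class = "cooccurrence_table")
}

#' Per-attribute sentence co-occurrence counts
#' @param table A `cooccurrence_table`.
#' @return Named integer vector of distinct-sentence counts.
#' @export
cooccurrence_counts <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  vapply(table$sentence_sets, length, 0L)
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cnt <- cooccurrence_counts(x)
  cat("<cooccurrence_table>\n")
  for (a in names(sort(-cnt))) cat(sprintf("  %-18s %d\n", a, cnt[[a]]))
  invisible(x)
}

#' Filter candidate attributes by co-occurrence support
#'
#' Keeps attributes co-occurring with phenotypes in at least `min_sentences`
#' distinct sentences across the corpus (default 2). The result is a
#' candidate list for human curation, sorted by descending count then name.
#'
#' @param table A `cooccurrence_table`.
#' @param min_sentences Minimum number of distinct supporting sentences.
#' @return Character vector of attribute names.
#' @export
filter_candidate_attributes <- function(table, min_sentences = 2L) {
  stopifnot(min_sentences >= 1L)
  cnt <- cooccurrence_counts(table)
  keep <- cnt[cnt >= min_sentences]
  names(keep)[order(-keep, names(keep))]
}
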