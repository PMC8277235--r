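# Context feature encoding for attribute value prediction: the context of a
# phenotype (its sentence) is encoded, per trigger term of the attribute's
# value set, as a presence flag and the signed token distance from the
# nearest occurrence of the trigger to the phenotype (negative = trigger to
# the left). Distance is the difference between the facing token indices
# (a trigger ending two tokens before the phenotype has distance -2); a
# trigger overlapping the phenotype has distance 0, and the presence flag
# disambiguates absence from adjacency.

attribute_trigger_terms <- function(attribute) {
  unlist(attribute$triggers, use.names = FALSE)
}

# Value label behind each trigger term, aligned with
# attribute_trigger_terms() order.
attribute_trigger_values <- function(attribute) {
  rep(names(attribute$triggers), lengths(attribute$triggers))
}

# Internal representation used by the classifiers: the public per-trigger
# presence/distance vector, augmented with per-value aggregates (presence of
# any trigger of the value, and the distance of its nearest occurrence), so
# a trigger term unseen in training still projects onto the value-level
# features its siblings trained. Derivable from the public vector alone.
augment_trigger_features <- function(features, trigger_values) {
  values <- unique(trigger_values)
  agg <- matrix(0, nrow = nrow(features), ncol = 2L * length(values),
                dimnames = list(NULL, as.vector(rbind(
                  paste0("value:", values, ".presence"),
                  paste0("value:", values, ".dist")))))
  for (k in seq_along(values)) {
    idx <- which(trigger_values == values[k])
    pres_cols <- 2L * idx - 1L
    dist_cols <- 2L * idx
    for (r in seq_len(nrow(features))) {
      on <- features[r, pres_cols] != 0
      if (!any(on)) next
      d <- features[r, dist_cols][on]
      agg[r, 2L * k - 1L] <- 1
      agg[r, 2L * k] <- d[which.min(abs(d))]
    }
  }
  cbind(features, agg)
}

# Token indices (1-based first/last) of each occurrence of a (possibly
# multi-word) term within a token sequence; case-insensitive.
term_token_occurrences <- function(tokens_lower, term) {
  term_toks <- tolower(tokenize(term)$token)
  k <- length(term_toks)
  n <- length(tokens_lower)
  if (k == 0L || n < k) return(NULL)
  starts <- which(tokens_lower == term_toks[1])
  hits <- starts[vapply(starts, function(s) {
    s + k - 1L <= n && all(tokens_lower[s:(s + k - 1L)] == term_toks)
  }, NA)]
  if (!length(hits)) return(NULL)
  cbind(first = hits, last = hits + k - 1L)
}

#' Encode a phenotype's sentence context for one attribute
#'
#' @param sentence_tokens Character vector of sentence tokens.
#' @param phenotype_token_span Integer pair `c(first, last)`: 1-based token
#'   indices of the phenotype within the sentence.
#' @param attribute An attribute definition from [schema_attribute()].
#' @param window Maximum absolute token distance; trigger occurrences farther
#'   away are treated as absent. Default: unlimited (whole sentence).
#' @return Named numeric vector of length 2 x (number of trigger terms):
#'   `<trigger>.presence` and `<trigger>.dist` per trigger.
#' @export
encode_context <- function(sentence_tokens, phenotype_token_span, attribute,
                           window = Inf) {
  p1 <- phenotype_token_span[1]; p2 <- phenotype_token_span[2]
  stopifnot(p1 >= 1L, p2 >= p1, p2 <= length(sentence_tokens))
  toks <- tolower(sentence_tokens)
  triggers <- attribute_trigger_terms(attribute)
  out <- numeric(2L * length(triggers))
  names(out) <- as.vector(rbind(paste0(triggers, ".presence"),
                                paste0(triggers, ".dist")))
  for (i in seq_along(triggers)) {
    occ <- term_token_occurrences(toks, triggers[i])
    if (is.null(occ)) next
    d <- ifelse(occ[, "last"] < p1, occ[, "last"] - p1,
                ifelse(occ[, "first"] > p2, occ[, "first"] - p2, 0))
    d <- d[abs(d) <= window]
    if (!length(d)) next
    best <- d[which.min(abs(d))]
    out[2L * i - 1L] <- 1
    out[2L * i] <- best
  }
  out
}

# Locate the token span of a character interval within a sentence.
char_span_to_token_span <- function(tokens, rel_start, rel_end) {
  hit <- which(tokens$start < rel_end & tokens$end > rel_start)
  if (!length(hit)) return(NULL)
  c(min(hit), max(hit))
}

#' Build training examples for one attribute from gold-annotated documents
#'
#' For every gold phenotype instance, encodes its sentence context for the
#' attribute and pairs it with the gold value label.
#'
#' @param corpus List of documents, each a list with `text` and `ann` (a
#'   `standoff_document`), as produced by [generate_corpus()].
#' @param schema A `phenossu_schema`.
#' @param attribute_name Name of the attribute to build examples for.
#' @param window Token window passed to [encode_context()].
#' @return list(features = numeric matrix, labels = character vector).
#' @export
attribute_training_data <- function(corpus, schema, attribute_name,
                                    window = Inf) {
  attribute <- schema_attribute(schema, attribute_name)
  feats <- list(); labels <- character()
  for (doc in corpus) {
    sents <- split_sentences(doc$text)
    tok_cache <- lapply(sents$sentence, tokenize)
    insts <- to_instances(doc$ann, schema)
    for (inst in insts) {
      si <- inst$sentence_ref$sentence
      if (is.na(si)) next
      toks <- tok_cache[[si]]
      tspan <- char_span_to_token_span(
        toks, inst$concept$start - sents$start[si],
        inst$concept$end - sents$start[si])
      if (is.null(tspan)) next
      feats[[length(feats) + 1L]] <-
        encode_context(toks$token, tspan, attribute, window)
      labels <- c(labels, inst$values[[attribute_name]])
    }
  }
  list(features = do.call(rbind, feats), labels = labels)
}
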