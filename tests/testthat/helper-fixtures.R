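# Shared fixtures and independent oracles. Expensive fixtures (the trained
# classifier set) are built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_schema <- function() {
  if (is.null(.fixture_cache$schema)) .fixture_cache$schema <- load_schema()
  .fixture_cache$schema
}

fixture_lexicon <- function() {
  if (is.null(.fixture_cache$lexicon)) {
    .fixture_cache$lexicon <- load_lexicon()
  }
  .fixture_cache$lexicon
}

# Recovery-regime corpus: 200 sentences, unambiguous, every attribute at
# prevalence 0.3 so each value is represented in both splits.
fixture_recovery <- function() {
  if (is.null(.fixture_cache$recovery)) {
    schema <- fixture_schema()
    lexicon <- fixture_lexicon()
    cfg <- generator_config(n_documents = 20, sentences_per_document = 10,
                            prevalence = 0.3, ambiguity = 0, seed = 20260921)
    corpus <- generate_corpus(cfg, schema, lexicon)
    train_docs <- corpus[1:12]
    test_docs <- corpus[13:20]
    classifiers <- train_phenossu_classifiers(train_docs, schema, seed = 7)
    gold_test <- do.call(c, lapply(test_docs, function(d)
      to_instances(d$ann, schema)))
    pred_test <- do.call(c, lapply(test_docs, function(d)
      extract_phenossu(d$text, lexicon, classifiers, schema,
                       doc_id = d$doc_id)$instances))
    .fixture_cache$recovery <- list(
      corpus = corpus, train_docs = train_docs, test_docs = test_docs,
      classifiers = classifiers, gold_test = gold_test,
      pred_test = pred_test)
  }
  .fixture_cache$recovery
}

# A tiny hand-written document + annotation used across BRAT tests.
fixture_tiny_doc <- function() {
  text <- "Patients develop severe bleeding in the nose. Rash may occur."
  ann <- paste(
    "T1\tPhenotype 24 32\tbleeding",
    "T2\tFindingSite 40 44\tnose",
    "T3\tPhenotype 46 50\tRash",
    "A1\tseverity T1 severe",
    "A2\tassertion T3 possible",
    "R1\tlocate Arg1:T1 Arg2:T2",
    sep = "\n")
  list(text = text, ann = ann)
}

# ---- independent oracles ----

# Exhaustive maximum matching over the overlap graph: recursion over
# predictions, trying every free overlapping gold or skipping.
oracle_max_matching <- function(pred, gold) {
  np <- nrow(pred); ng <- nrow(gold)
  if (np == 0L || ng == 0L) return(0L)
  overlaps <- lapply(seq_len(np), function(u)
    which(gold$start < pred$end[u] & gold$end > pred$start[u]))
  best <- function(u, used) {
    if (u > np) return(0L)
    res <- best(u + 1L, used)            # leave prediction u unmatched
    for (v in setdiff(overlaps[[u]], used)) {
      res <- max(res, 1L + best(u + 1L, c(used, v)))
    }
    res
  }
  best(1L, integer())
}

# Naive sentence x attribute x trigger recount of co-occurrence counts.
oracle_cooccurrence_counts <- function(corpus, lexicon, schema) {
  counts <- stats::setNames(integer(length(schema$attributes)),
                            attribute_names(schema))
  if (is.null(names(corpus))) {
    names(corpus) <- sprintf("doc%03d", seq_along(corpus))
  }
  for (doc_id in names(corpus)) {
    sents <- split_sentences(corpus[[doc_id]])
    for (i in seq_len(nrow(sents))) {
      sent <- sents$sentence[i]
      has_pheno <- FALSE
      for (term in lexicon$entries$term) {
        pat <- paste0("(?<![[:alnum:]])",
                      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                      "(?![[:alnum:]])")
        if (grepl(pat, sent, perl = TRUE, ignore.case = TRUE)) {
          has_pheno <- TRUE
          break
        }
      }
      if (!has_pheno) next
      for (a in schema$attributes) {
        hit <- FALSE
        for (trs in a$triggers) {
          for (tr in trs) {
            pat <- paste0("(?<![[:alnum:]])",
                          gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tr),
                          "(?![[:alnum:]])")
            pat <- gsub("[[:space:]]+", "[[:space:]]+", pat)
            if (grepl(pat, sent, perl = TRUE, ignore.case = TRUE)) {
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
        if (hit) counts[[a$name]] <- counts[[a$name]] + 1L
      }
    }
  }
  counts
}

random_spans <- function(n, max_pos = 300L, max_len = 15L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(start = start, end = start + len)
}

# Write a temporary schema YAML and return its path.
write_schema_yaml <- function(attributes, version = "test") {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(version = version, attributes = attributes), path)
  path
}
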