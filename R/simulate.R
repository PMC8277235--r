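# Seeded generator of guideline-like corpora with exact gold annotations.
# Sentences are assembled from templates (opener + planted trigger terms +
# phenotype mention + optional finding site), so gold spans and attribute
# values are exact by construction; no attempt is made to mimic real prose
# beyond trigger/phenotype placement.

#' Create a corpus generator configuration
#'
#' @param n_documents,sentences_per_document Corpus dimensions.
#' @param prevalence Per-attribute probability that a sentence's phenotype
#'   carries a non-default value of that attribute. Either a single number,
#'   or a named vector over schema attribute names; `NULL` uses the
#'   corpus-emulation defaults (assertion/frequency 0.25; age specificity,
#'   severity and temporal pattern 0.15; other attributes 0.05, i.e. about
#'   1.3 non-default values per instance).
#' @param ambiguity Probability that a planted trigger term appears without
#'   its attribute applying (the gold value stays default). 0 = unambiguous.
#' @param disagreement_rate Per-instance perturbation probability used by
#'   [generate_annotator_pair()].
#' @param phenotype_rate Probability that a sentence mentions a phenotype.
#' @param site_rate Probability that a phenotype gets a finding site.
#' @param seed Mandatory integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_documents = 10L, sentences_per_document = 10L,
                             prevalence = NULL, ambiguity = 0,
                             disagreement_rate = 0.1, phenotype_rate = 0.9,
                             site_rate = 0.15, seed) {
  if (missing(seed) || length(seed) != 1L || is.na(suppressWarnings(
    as.integer(seed)))) {
    stop("an integer seed is mandatory")
  }
  rates <- c(ambiguity = ambiguity, disagreement_rate = disagreement_rate,
             phenotype_rate = phenotype_rate, site_rate = site_rate,
             unlist(prevalence))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 prevalence = prevalence, ambiguity = ambiguity,
                 disagreement_rate = disagreement_rate,
                 phenotype_rate = phenotype_rate, site_rate = site_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

default_prevalence <- function(schema) {
  p <- stats::setNames(rep(0.05, length(schema$attributes)),
                       attribute_names(schema))
  common <- c(assertion = 0.25, frequency = 0.25, age_specificity = 0.15,
              severity = 0.15, temporal_pattern = 0.15)
  p[intersect(names(common), names(p))] <-
    common[intersect(names(common), names(p))]
  p
}

resolve_prevalence <- function(config, schema) {
  nm <- attribute_names(schema)
  if (is.null(config$prevalence)) return(default_prevalence(schema))
  p <- config$prevalence
  if (length(p) == 1L && is.null(names(p))) {
    return(stats::setNames(rep(p, length(nm)), nm))
  }
  out <- stats::setNames(rep(0, length(nm)), nm)
  out[names(p)] <- unlist(p)
  out
}

#' Generate a synthetic guideline corpus with gold annotations
#'
#' Deterministic given the configuration seed: identical configurations
#' produce byte-identical corpora. Each generated sentence optionally
#' mentions one phenotype from the lexicon; per attribute, with the
#' configured prevalence, a trigger term of a randomly chosen non-default
#' value is planted in the sentence and (unless suppressed by the ambiguity
#' rate) the gold annotation records that value.
#'
#' @param config A [generator_config()].
#' @param schema A `phenossu_schema`.
#' @param lexicon A `phenotype_lexicon` of phenotype terms.
#' @param site_lexicon A `phenotype_lexicon` of finding-site terms.
#' @return List of documents, each `list(doc_id, text, ann)` with `ann` a
#'   gold `standoff_document`; carries a `gold_summary` attribute
#'   (data.frame of planted non-default values, including ambiguous plants).
#' @export
generate_corpus <- function(config, schema = load_schema(),
                            lexicon = load_lexicon(),
                            site_lexicon = load_lexicon(
                              system.file("extdata", "finding_sites.tsv",
                                          package = "phenossu",
                                          mustWork = TRUE))) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  prevalence <- resolve_prevalence(config, schema)
  openers <- c("Patients develop", "The disease causes",
               "Clinical examination reveals",
               "Affected individuals experience")
  filler <- "The condition requires supportive care and monitoring."
  presence_first <- vapply(schema$attributes, function(a)
    a$category == "presence", NA)
  docs <- vector("list", config$n_documents)
  summary_rows <- list()
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    pieces <- character()     # sentence strings
    offset <- 0L
    entities <- list(); attrs <- list(); rels <- list()
    t_id <- 0L; a_id <- 0L; r_id <- 0L
    for (s in seq_len(config$sentences_per_document)) {
      if (stats::runif(1) >= config$phenotype_rate) {
        sent <- filler
      } else {
        pheno_i <- sample(nrow(lexicon$entries), 1L)
        pheno <- lexicon$entries[pheno_i, ]
        planted <- list()
        for (a in schema$attributes) {
          if (stats::runif(1) >= prevalence[[a$name]]) next
          cand <- setdiff(names(a$triggers)[vapply(a$triggers, length, 0L) >
                                              0L], a$default)
          if (!length(cand)) next
          value <- if (length(cand) == 1L) cand else sample(cand, 1L)
          trig <- a$triggers[[value]]
          trig <- if (length(trig) == 1L) trig else sample(trig, 1L)
          ambiguous <- stats::runif(1) < config$ambiguity
          planted[[length(planted) + 1L]] <-
            list(attribute = a$name, value = value, trigger = trig,
                 ambiguous = ambiguous,
                 presence = a$category == "presence")
          summary_rows[[length(summary_rows) + 1L]] <- data.frame(
            doc_id = doc_id, sentence = s, attribute = a$name,
            value = value, ambiguous = ambiguous, stringsAsFactors = FALSE)
        }
        pre <- vapply(Filter(function(p) p$presence, planted),
                      `[[`, "", "trigger")
        post <- vapply(Filter(function(p) !p$presence, planted),
                       `[[`, "", "trigger")
        chunks <- c(sample(openers, 1L), pre, post, pheno$term)
        with_site <- stats::runif(1) < config$site_rate &&
          nrow(site_lexicon$entries) > 0L
        site <- NULL
        if (with_site) {
          site <- site_lexicon$entries[sample(nrow(site_lexicon$entries),
                                              1L), ]
          chunks <- c(chunks, "in the", site$term)
        }
        sent <- paste0(paste(chunks, collapse = " "), ".")
        # character offsets of the phenotype (and site) chunk within sentence
        before_pheno <- paste(chunks[seq_len(length(chunks) -
                                               if (with_site) 3L else 1L)],
                              collapse = " ")
        p_start <- offset + nchar(before_pheno) + 1L
        p_end <- p_start + nchar(pheno$term)
        t_id <- t_id + 1L
        pheno_tid <- paste0("T", t_id)
        entities[[length(entities) + 1L]] <-
          list(id = pheno_tid, type = "Phenotype",
               spans = data.frame(start = p_start, end = p_end),
               text = pheno$term)
        for (p in planted) {
          if (p$ambiguous) next
          a_id <- a_id + 1L
          attrs[[length(attrs) + 1L]] <-
            list(id = paste0("A", a_id), name = p$attribute,
                 target = pheno_tid, value = p$value)
        }
        if (with_site) {
          s_start <- p_end + nchar(" in the ")
          s_end <- s_start + nchar(site$term)
          t_id <- t_id + 1L
          entities[[length(entities) + 1L]] <-
            list(id = paste0("T", t_id), type = "FindingSite",
                 spans = data.frame(start = s_start, end = s_end),
                 text = site$term)
          r_id <- r_id + 1L
          rels[[length(rels) + 1L]] <-
            list(id = paste0("R", r_id), type = "locate",
                 arg1 = pheno_tid, arg2 = paste0("T", t_id))
        }
      }
      pieces <- c(pieces, sent)
      offset <- offset + nchar(sent) + 1L   # sentences joined by one space
    }
    text <- paste(pieces, collapse = " ")
    docs[[d]] <- list(doc_id = doc_id, text = text,
                      ann = new_standoff_document(doc_id, text, entities,
                                                  attrs, rels))
  }
  attr(docs, "gold_summary") <- if (length(summary_rows))
    do.call(rbind, summary_rows)
  else data.frame(doc_id = character(), sentence = integer(),
                  attribute = character(), value = character(),
                  ambiguous = logical(), stringsAsFactors = FALSE)
  docs
}

#' Simulate a pair of independent annotators
#'
#' Annotator A returns the gold annotations unchanged; annotator B perturbs
#' each phenotype instance independently with the given probability — with
#' weight 0.9 an attribute value flip within the value set (guaranteed to
#' change), with weight 0.1 a one-token span shift. Supports testing the
#' merging and agreement machinery.
#'
#' @param corpus Output of [generate_corpus()].
#' @param disagreement_rate Per-instance perturbation probability.
#' @param seed Integer seed.
#' @param schema A `phenossu_schema`.
#' @return list(docs_a =, docs_b =), each a list of documents like the input.
#' @export
generate_annotator_pair <- function(corpus, disagreement_rate, seed,
                                    schema = load_schema()) {
  stopifnot(disagreement_rate >= 0, disagreement_rate <= 1)
  set.seed(seed)
  docs_b <- lapply(corpus, function(doc) {
    insts <- to_instances(doc$ann, schema)
    toks <- tokenize(doc$text)
    for (i in seq_along(insts)) {
      if (stats::runif(1) >= disagreement_rate) next
      inst <- insts[[i]]
      if (stats::runif(1) < 0.9) {           # attribute value flip
        a <- schema$attributes[[sample(length(schema$attributes), 1L)]]
        current <- inst$values[[a$name]]
        others <- setdiff(a$values$label, current)
        pick <- if (length(others) == 1L) others else sample(others, 1L)
        inst <- set_attribute(inst, a$name, pick, schema)
      } else {                               # span shift by one token
        prev <- toks[toks$end <= inst$concept$start, , drop = FALSE]
        nxt <- toks[toks$start >= inst$concept$end, , drop = FALSE]
        if (nrow(prev)) {
          new_start <- prev$start[nrow(prev)]
          new_end <- inst$concept$end
        } else if (nrow(nxt)) {
          new_start <- inst$concept$start
          new_end <- nxt$end[1]
        } else {
          new_start <- inst$concept$start; new_end <- inst$concept$end
        }
        surface <- span_text(doc$text, new_start, new_end)
        inst$concept <- phenotype_concept(surface, new_start, new_end,
                                          inst$concept$snomed_code,
                                          inst$concept$preferred_label,
                                          doc_text = doc$text)
        inst$spans <- data.frame(start = new_start, end = new_end)
      }
      insts[[i]] <- inst
    }
    list(doc_id = doc$doc_id, text = doc$text,
         ann = instances_to_standoff(insts, doc$doc_id, doc$text, schema))
  })
  list(docs_a = corpus, docs_b = docs_b)
}

#' Generate a gold corpus with fixed representability composition
#'
#' Emits exactly the requested number of instances per representability
#' category, so profile-comparison arithmetic can be checked in closed form:
#' \describe{
#'   \item{concept_only}{all-default, full fidelity: precise under every
#'     profile.}
#'   \item{fhir_only}{a severity value: precise under profiles containing
#'     `severity`.}
#'   \item{cem_only}{an assertion value: precise under profiles containing
#'     `assertion`.}
#'   \item{phenossu_only}{a temporal-pattern value: precise only under the
#'     full schema profile.}
#'   \item{partial}{fidelity flag `partial`: precise under no profile.}
#' }
#'
#' @param counts Named integer vector over (a subset of) the five category
#'   names above.
#' @param schema A `phenossu_schema` (must define assertion, severity and
#'   temporal_pattern).
#' @return List of `phenossu_instance` objects.
#' @export
generate_expressiveness_corpus <- function(counts, schema = load_schema()) {
  known <- c("concept_only", "fhir_only", "cem_only", "phenossu_only",
             "partial")
  if (is.null(names(counts)) || !all(names(counts) %in% known)) {
    stop("counts must be named with: ", paste(known, collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  base <- new_instance(phenotype_concept("fever", 0L, 5L, "386661006",
                                         "Fever"), schema)
  make <- function(category) {
    switch(category,
      concept_only = base,
      fhir_only = set_attribute(base, "severity", "severe", schema),
      cem_only = set_attribute(base, "assertion", "possible", schema),
      phenossu_only = set_attribute(base, "temporal_pattern", "acute",
                                    schema),
      partial = { x <- base; x$equal_to_original <- "partial"; x })
  }
  out <- list()
  for (category in names(counts)) {
    n <- as.integer(counts[[category]])
    if (n > 0L) out <- c(out, rep(list(make(category)), n))
  }
  out
}
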