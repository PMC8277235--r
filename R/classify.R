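#' Synthetic minority oversampling of training examples
#'
#' Equalizes class counts to the majority class by interpolating new feature
#' vectors between randomly chosen same-class examples (a SMOTE-style
#' scheme); a class with a single example is duplicated. Deterministic given
#' the seed.
#'
#' @param features Numeric matrix, one row per example.
#' @param labels Character/factor vector of class labels.
#' @param seed Integer seed.
#' @return list(features =, labels =) with equal class counts. Single-class
#'   input is returned unchanged with a warning.
#' @export
oversample_minority <- function(features, labels, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) {
    warning("single-class input: nothing to oversample")
    return(list(features = features, labels = labels))
  }
  set.seed(seed)
  target <- max(counts)
  add_feats <- list(); add_labels <- character()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0L) next
    rows <- which(labels == cls)
    i <- rows[sample.int(length(rows), need, replace = TRUE)]
    j <- rows[sample.int(length(rows), need, replace = TRUE)]
    u <- stats::runif(need)
    synth <- features[i, , drop = FALSE] +
      u * (features[j, , drop = FALSE] - features[i, , drop = FALSE])
    add_feats[[length(add_feats) + 1L]] <- synth
    add_labels <- c(add_labels, rep(cls, need))
  }
  list(features = rbind(features, do.call(rbind, add_feats)),
       labels = c(labels, add_labels))
}

constant_classifier <- function(attribute_name, label, triggers, window) {
  structure(list(kind = "constant", attribute = attribute_name,
                 label = label, levels = label, triggers = triggers,
                 window = window, hyperparameters = NULL),
            class = "attribute_classifier")
}

#' Train a per-attribute value classifier
#'
#' Fits a max-margin (support vector) classifier on trigger presence/distance
#' features, after minority oversampling, with hyperparameters selected by
#' k-fold cross-validated grid search on the training examples only.
#' Deterministic given the seed. Degenerate inputs (a single class, or
#' constant features) yield a constant majority-class classifier with a
#' warning.
#'
#' @param features Numeric matrix from [attribute_training_data()].
#' @param labels Gold value labels (one per row).
#' @param attribute The attribute definition the examples belong to.
#' @param grid list(cost =, kernel =) hyperparameter grid.
#' @param seed Integer seed (oversampling and fold assignment).
#' @param n_folds Cross-validation folds.
#' @param window Token window the features were encoded with (stored for
#'   prediction time).
#' @return Object of class `attribute_classifier`.
#' @export
train_attribute_classifier <- function(features, labels, attribute,
                                       grid = list(cost = c(1, 10),
                                                   kernel = c("linear",
                                                              "radial")),
                                       seed = 1L, n_folds = 5L,
                                       window = Inf) {
  labels <- as.character(labels)
  triggers <- attribute_trigger_terms(attribute)
  if (is.null(features) || nrow(features) == 0L) {
    warning("no training examples for '", attribute$name,
            "': constant default classifier")
    return(constant_classifier(attribute$name, attribute$default, triggers,
                               window))
  }
  stopifnot(ncol(features) == 2L * length(triggers))
  majority <- names(sort(-table(labels)))[1]
  if (length(unique(labels)) < 2L) {
    warning("single-class training data for '", attribute$name,
            "': constant classifier")
    return(constant_classifier(attribute$name, majority, triggers, window))
  }
  if (all(apply(features, 2, function(col) length(unique(col)) == 1L))) {
    warning("constant features for '", attribute$name,
            "': constant majority classifier")
    return(constant_classifier(attribute$name, majority, triggers, window))
  }
  trigger_values <- attribute_trigger_values(attribute)
  bal <- oversample_minority(augment_trigger_features(features,
                                                      trigger_values),
                             labels, seed = seed)
  x <- bal$features
  y <- factor(bal$labels)
  set.seed(seed + 1L)
  folds <- sample(rep_len(seq_len(n_folds), nrow(x)))
  combos <- expand.grid(cost = grid$cost, kernel = grid$kernel,
                        stringsAsFactors = FALSE)
  cv_acc <- vapply(seq_len(nrow(combos)), function(g) {
    acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        kernel = combos$kernel[g], cost = combos$cost[g],
                        scale = FALSE)
      mean(as.character(stats::predict(fit, x[!tr, , drop = FALSE])) ==
             as.character(y[!tr]))
    }, NA_real_)
    mean(acc, na.rm = TRUE)
  }, NA_real_)
  best <- which.max(cv_acc)
  model <- e1071::svm(x, y, kernel = combos$kernel[best],
                      cost = combos$cost[best], scale = FALSE)
  structure(list(kind = "svm", attribute = attribute$name, model = model,
                 hyperparameters = as.list(combos[best, ]),
                 cv_accuracy = cv_acc[best], levels = levels(y),
                 default = attribute$default, triggers = triggers,
                 trigger_values = trigger_values, window = window),
            class = "attribute_classifier")
}

#' @export
print.attribute_classifier <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("<attribute_classifier '%s': constant '%s'>\n", x$attribute,
                x$label))
  } else {
    cat(sprintf(
      "<attribute_classifier '%s': svm %s cost=%g, cv acc %.3f, labels {%s}>\n",
      x$attribute, x$hyperparameters$kernel, x$hyperparameters$cost,
      x$cv_accuracy, paste(x$levels, collapse = ", ")))
  }
  invisible(x)
}

#' Predict attribute values from context features
#'
#' An all-zero feature vector (no trigger in context) always yields the
#' attribute's default value; otherwise the fitted model decides among the
#' labels seen in training.
#'
#' @param classifier An `attribute_classifier`.
#' @param features Numeric vector, or matrix with one row per case, with the
#'   training dimensionality (input error otherwise).
#' @return Character vector of predicted value labels.
#' @export
predict_value <- function(classifier, features) {
  stopifnot(inherits(classifier, "attribute_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != 2L * length(classifier$triggers)) {
    stop("feature dimensionality mismatch: got ", ncol(features),
         ", expected ", 2L * length(classifier$triggers))
  }
  if (classifier$kind == "constant") {
    return(rep(classifier$label, nrow(features)))
  }
  out <- rep(classifier$default %||% classifier$levels[1], nrow(features))
  nonzero <- rowSums(features != 0) > 0
  if (any(nonzero)) {
    x <- augment_trigger_features(features[nonzero, , drop = FALSE],
                                  classifier$trigger_values)
    out[nonzero] <- as.character(stats::predict(classifier$model, x))
  }
  out
}

#' Default-value reference predictor
#'
#' The reference model that ignores context entirely: `present` for the
#' assertion attribute and `none` for every other attribute (i.e. the schema
#' default).
#'
#' @param attribute An attribute definition from [schema_attribute()].
#' @return The default value label.
#' @export
default_baseline_predict <- function(attribute) {
  attribute$default
}

#' Train classifiers for all schema attributes
#'
#' @param corpus Gold-annotated documents as for [attribute_training_data()].
#' @param schema A `phenossu_schema`.
#' @param seed Integer seed; per-attribute seeds are derived from it.
#' @param window Token window for feature encoding.
#' @param grid Hyperparameter grid, as in [train_attribute_classifier()].
#' @return Named list of `attribute_classifier` objects, one per attribute.
#' @export
train_phenossu_classifiers <- function(corpus, schema, seed = 1L,
                                       window = Inf,
                                       grid = list(cost = c(1, 10),
                                                   kernel = c("linear",
                                                              "radial"))) {
  out <- list()
  for (i in seq_along(schema$attributes)) {
    a <- schema$attributes[[i]]
    dat <- attribute_training_data(corpus, schema, a$name, window)
    out[[a$name]] <- suppressWarnings(
      train_attribute_classifier(dat$features, dat$labels, a, grid = grid,
                                 seed = seed + i, window = window))
  }
  out
}

#' Extract a phenotype knowledge graph from free text
#'
#' The hybrid strategy: recognize phenotype concepts with the dictionary
#' matcher, then predict every attribute's value from the sentence context
#' with the trained per-attribute classifiers (attributes without a
#' classifier fall back to the default-value reference model). Each
#' recognized concept yields one instance with a full attribute assignment
#' and a SNOMED normalization.
#'
#' @param doc_text Document text.
#' @param lexicon A `phenotype_lexicon`.
#' @param classifiers Named list of `attribute_classifier` objects (possibly
#'   partial or empty).
#' @param schema A `phenossu_schema`.
#' @param window Token window for feature encoding.
#' @param doc_id,disease_name Identifiers recorded in the graph.
#' @return A `phenossu_graph` (empty for degenerate inputs).
#' @export
extract_phenossu <- function(doc_text, lexicon, classifiers = list(),
                             schema, window = Inf, doc_id = "doc",
                             disease_name = doc_id) {
  if (is.null(doc_text) || !nzchar(trimws(doc_text))) {
    return(phenotype_graph(disease_name, doc_id))
  }
  sents <- split_sentences(doc_text)
  tok_cache <- lapply(sents$sentence, tokenize)
  concepts <- recognize(doc_text, lexicon)
  instances <- list()
  for (concept in concepts) {
    si <- which(sents$start <= concept$start & concept$start < sents$end)
    si <- if (length(si)) si[1] else NA_integer_
    inst <- new_instance(concept, schema,
                         sentence_ref = list(doc_id = doc_id, sentence = si))
    if (!is.na(si)) {
      toks <- tok_cache[[si]]
      tspan <- char_span_to_token_span(toks,
                                       concept$start - sents$start[si],
                                       concept$end - sents$start[si])
      for (a in schema$attributes) {
        clf <- classifiers[[a$name]]
        value <- if (is.null(clf)) default_baseline_predict(a)
                 else predict_value(clf, encode_context(toks$token, tspan, a,
                                                        window))
        inst <- set_attribute(inst, a$name, value, schema)
      }
    }
    inst$normalized <- normalize_concept(concept, lexicon = lexicon)
    instances[[length(instances) + 1L]] <- inst
  }
  phenotype_graph(disease_name, doc_id, instances)
}
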