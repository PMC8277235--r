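as_span_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    return(x[c("start", "end")])
  }
  if (length(x) == 0L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(x, `[[`, 0L, "start"),
             end = vapply(x, `[[`, 0L, "end"))
}

#' Overlap-based span precision, recall and F1
#'
#' A predicted span counts as a true positive if it can be aligned one-to-one
#' with a gold span it overlaps; the alignment is a maximum-cardinality
#' matching over the overlap graph. Unmatched predictions are false
#' positives, unmatched gold spans false negatives. F1 is the harmonic mean
#' of precision and recall; zero-denominator conventions give 0 when there
#' are no true positives.
#'
#' @param predicted,gold Span sets: data.frames with `start`/`end` columns
#'   (0-based, end-exclusive) or lists of `phenotype_concept` objects.
#' @return Object of class `span_eval`: list(tp, fp, fn, precision, recall,
#'   f1).
#' @export
span_overlap_f1 <- function(predicted, gold) {
  p <- as_span_frame(predicted)
  g <- as_span_frame(gold)
  np <- nrow(p); ng <- nrow(g)
  tp <- 0L
  if (np > 0L && ng > 0L) {
    # adjacency via interval sweep; candidates ordered by decreasing overlap
    adj <- vector("list", np)
    for (u in seq_len(np)) {
      cand <- which(g$start < p$end[u] & g$end > p$start[u])
      if (length(cand)) {
        ov <- overlap_length(p$start[u], p$end[u], g$start[cand], g$end[cand])
        adj[[u]] <- cand[order(-ov)]
      } else adj[[u]] <- integer()
    }
    tp <- sum(kuhn_matching(adj, ng) != 0L)
  }
  fp <- np - tp
  fn <- ng - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (tp > 0L) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "span_eval")
}

#' @export
print.span_eval <- function(x, ...) {
  cat(sprintf("<span_eval TP=%d FP=%d FN=%d  P=%.3f R=%.3f F1=%.3f>\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Prevalence-weighted (balanced) accuracy for one attribute
#'
#' Mean of per-class recalls over the classes present in the gold sequence,
#' so a model is rewarded for predicting rare values, not just the dominant
#' default. Classes absent from gold are excluded.
#'
#' @param predictions,gold Aligned label vectors.
#' @return Proportion in \[0, 1\].
#' @export
weighted_accuracy <- function(predictions, gold) {
  gold <- as.character(gold); predictions <- as.character(predictions)
  if (length(gold) == 0L) stop("weighted accuracy undefined on empty gold")
  stopifnot(length(predictions) == length(gold))
  classes <- unique(gold)
  recalls <- vapply(classes, function(cls) {
    idx <- gold == cls
    mean(predictions[idx] == cls)
  }, NA_real_)
  mean(recalls)
}

#' Average weighted accuracy across attributes
#'
#' @param per_attribute_results Numeric vector (or list) of per-attribute
#'   weighted accuracies.
#' @return Their unweighted mean.
#' @export
average_weighted_accuracy <- function(per_attribute_results) {
  x <- unlist(per_attribute_results)
  if (length(x) == 0L) stop("no attribute results to average")
  mean(x)
}

#' Per-attribute weighted accuracies of predicted vs gold instances
#'
#' Aligns predicted and gold instances by identical concept spans and
#' computes [weighted_accuracy()] per attribute plus the overall average.
#'
#' @param predicted,gold Lists of `phenossu_instance` objects over the same
#'   documents.
#' @param schema A `phenossu_schema`.
#' @return list(per_attribute = named numeric, awa = numeric, n_aligned =).
#' @export
attribute_accuracy <- function(predicted, gold, schema) {
  key <- function(inst) paste(inst$sentence_ref$doc_id, inst$concept$start,
                              inst$concept$end)
  pk <- vapply(predicted, key, "")
  gk <- vapply(gold, key, "")
  common <- intersect(pk, gk)
  if (!length(common)) stop("no span-aligned instances to evaluate")
  pi <- predicted[match(common, pk)]
  gi <- gold[match(common, gk)]
  per <- vapply(attribute_names(schema), function(a) {
    weighted_accuracy(vapply(pi, function(x) x$values[[a]], ""),
                      vapply(gi, function(x) x$values[[a]], ""))
  }, NA_real_)
  list(per_attribute = per, awa = average_weighted_accuracy(per),
       n_aligned = length(common))
}

#' Inter-annotation agreement at the instance level
#'
#' Items are the union of span-keyed instances from the two annotation sets;
#' each annotator's rating of an item is its full attribute-value tuple (or
#' "missing" when the annotator did not annotate that span). Returns the raw
#' agreement proportion (fraction of items with identical ratings, i.e. the
#' merge rule's `agree` verdict) and Cohen's kappa, with expected agreement
#' from the two marginal rating distributions.
#'
#' @param instances_a,instances_b Lists of `phenossu_instance` objects over
#'   the same documents.
#' @param schema A `phenossu_schema`.
#' @return list(kappa, raw_agreement, n_items, n_agree).
#' @export
instance_kappa <- function(instances_a, instances_b, schema) {
  rating <- function(inst) paste(inst$values[attribute_names(schema)],
                                 collapse = "|")
  key <- function(inst) paste(inst$sentence_ref$doc_id %||% "",
                              inst$concept$start, inst$concept$end)
  ka <- vapply(instances_a, key, "")
  kb <- vapply(instances_b, key, "")
  items <- union(ka, kb)
  if (length(items) == 0L) stop("agreement undefined on an empty union")
  ra <- ifelse(items %in% ka,
               vapply(instances_a[match(items, ka)], rating, ""),
               "<missing>")
  rb <- ifelse(items %in% kb,
               vapply(instances_b[match(items, kb)], rating, ""),
               "<missing>")
  n <- length(items)
  po <- mean(ra == rb)
  labs <- union(ra, rb)
  pa <- table(factor(ra, levels = labs)) / n
  pb <- table(factor(rb, levels = labs)) / n
  pe <- sum(pa * pb)
  kappa <- if (po == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, raw_agreement = po, n_items = n,
       n_agree = sum(ra == rb))
}

#' Rate of precise (full-fidelity) representations
#'
#' Fraction of instances whose annotation captures the full semantics of the
#' original description (`equal_to_original == "full"`).
#'
#' @param instances List of `phenossu_instance` objects.
#' @return list(count_full, count_total, percentage) with the percentage to
#'   one decimal place.
#' @export
precise_representation_rate <- function(instances) {
  if (length(instances) == 0L) stop("no instances")
  full <- sum(vapply(instances, function(x) x$equal_to_original == "full",
                     NA))
  list(count_full = full, count_total = length(instances),
       percentage = round(100 * full / length(instances), 1))
}

#' Concept-level coverage of a reference phenotype list
#'
#' Fraction of reference concept codes that appear among the annotated
#' concept codes (e.g. comparing annotated graphs against an external
#' knowledge base's phenotype lists).
#'
#' @param annotated_codes Character vector of annotated SNOMED codes.
#' @param reference_codes Character vector of reference SNOMED codes.
#' @return list(count_covered, count_total, percentage) with the percentage
#'   to one decimal place.
#' @export
concept_coverage <- function(annotated_codes, reference_codes) {
  reference_codes <- unique(reference_codes)
  if (length(reference_codes) == 0L) stop("empty reference set")
  covered <- sum(reference_codes %in% annotated_codes)
  list(count_covered = covered, count_total = length(reference_codes),
       percentage = round(100 * covered / length(reference_codes), 1))
}
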