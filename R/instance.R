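#' Create a phenotype concept mention
#'
#' @param surface_form Exact text of the mention.
#' @param start,end 0-based, end-exclusive character offsets.
#' @param snomed_code Normalized SNOMED-CT concept id ("" if unnormalizable).
#' @param preferred_label Preferred label of the concept.
#' @param doc_text Optional full document text; when given, the surface form
#'   is checked against the substring at the span.
#' @return Object of class `phenotype_concept`.
#' @export
phenotype_concept <- function(surface_form, start, end, snomed_code = "",
                              preferred_label = surface_form,
                              doc_text = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end)) {
    stop("invalid span [", start, ", ", end, ")")
  }
  if (!is.null(doc_text) && span_text(doc_text, start, end) != surface_form) {
    stop("surface form does not match document substring at [",
         start, ", ", end, ")")
  }
  structure(list(surface_form = surface_form, start = start, end = end,
                 snomed_code = as.character(snomed_code),
                 preferred_label = as.character(preferred_label)),
            class = "phenotype_concept")
}

#' Create a finding-site mention
#'
#' Finding sites are body structures linked to a phenotype (via `locate`
#' relations in the annotation), not attributes of it.
#'
#' @inheritParams phenotype_concept
#' @return Object of class `finding_site`.
#' @export
finding_site <- function(surface_form, start, end, snomed_code = "",
                         preferred_label = surface_form, doc_text = NULL) {
  x <- phenotype_concept(surface_form, start, end, snomed_code,
                         preferred_label, doc_text)
  class(x) <- "finding_site"
  x
}

#' Create a fresh phenotype instance with default attribute values
#'
#' A fresh instance carries the schema defaults for all attributes
#' (`assertion = present`, every other attribute `none`), agreement `agree`
#' and the original-description fidelity flag `full`.
#'
#' @param concept A [phenotype_concept()].
#' @param schema A `phenossu_schema`.
#' @param sentence_ref Optional list(doc_id, sentence) locating the mention.
#' @return Object of class `phenossu_instance`.
#' @export
new_instance <- function(concept, schema, sentence_ref = NULL) {
  stopifnot(inherits(concept, "phenotype_concept"),
            inherits(schema, "phenossu_schema"))
  structure(
    list(concept = concept,
         finding_sites = list(),
         normalized = NULL,
         values = schema_defaults(schema),
         agreement = "agree",
         equal_to_original = "full",
         sentence_ref = sentence_ref),
    class = "phenossu_instance")
}

#' Set one attribute value on an instance
#'
#' Enforces the closed vocabulary: the value must belong to the attribute's
#' value set declared in the schema.
#'
#' @param instance A `phenossu_instance`.
#' @param attribute Attribute name.
#' @param value Value label.
#' @param schema The `phenossu_schema` the instance was built against.
#' @return The updated instance; all other fields unchanged.
#' @export
set_attribute <- function(instance, attribute, value, schema) {
  stopifnot(inherits(instance, "phenossu_instance"))
  a <- schema_attribute(schema, attribute)
  if (!value %in% a$values$label) {
    stop("value '", value, "' is not in the closed value set of attribute '",
         attribute, "' {", paste(a$values$label, collapse = ", "), "}")
  }
  instance$values[[attribute]] <- value
  instance
}

#' Read one attribute value from an instance
#' @inheritParams set_attribute
#' @return The value label.
#' @export
get_attribute <- function(instance, attribute) {
  stopifnot(inherits(instance, "phenossu_instance"))
  v <- instance$values[[attribute]]
  if (is.null(v)) stop("unknown attribute: ", attribute)
  v
}

#' @export
print.phenossu_instance <- function(x, ...) {
  cat(sprintf("<phenossu_instance '%s' [%d,%d) %s>\n",
              x$concept$surface_form, x$concept$start, x$concept$end,
              x$concept$snomed_code))
  nd <- x$values[(names(x$values) == "assertion" & x$values != "present") |
                   (names(x$values) != "assertion" & x$values != "none")]
  if (length(nd)) {
    cat("  ", paste(names(nd), nd, sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Assemble a phenotype knowledge graph
#'
#' @param disease_name Name of the disease the document describes.
#' @param source_doc Document identifier.
#' @param instances List of `phenossu_instance` objects.
#' @return Object of class `phenossu_graph`.
#' @export
phenotype_graph <- function(disease_name, source_doc, instances = list()) {
  stopifnot(is.list(instances))
  for (inst in instances) {
    stopifnot(inherits(inst, "phenossu_instance"))
    ref <- inst$sentence_ref
    if (!is.null(ref) && !identical(ref$doc_id, source_doc)) {
      stop("instance sentence_ref points outside source document '",
           source_doc, "'")
    }
  }
  structure(list(disease_name = disease_name, source_doc = source_doc,
                 instances = instances),
            class = "phenossu_graph")
}

#' @export
print.phenossu_graph <- function(x, ...) {
  cat(sprintf("<phenossu_graph '%s' (%s): %d instances>\n", x$disease_name,
              x$source_doc, length(x$instances)))
  invisible(x)
}

#' Count attribute values that differ from the schema defaults
#'
#' @param x A `phenossu_graph`, a list of instances, or one instance.
#' @param schema The governing `phenossu_schema`.
#' @return Integer count of non-default attribute values.
#' @export
count_nondefault_values <- function(x, schema) {
  defaults <- schema_defaults(schema)
  insts <- if (inherits(x, "phenossu_graph")) x$instances
           else if (inherits(x, "phenossu_instance")) list(x)
           else x
  sum(vapply(insts, function(inst) {
    sum(inst$values[names(defaults)] != defaults)
  }, 0L))
}

instance_to_list <- function(inst) {
  list(
    concept = inst$concept[c("surface_form", "start", "end", "snomed_code",
                             "preferred_label")],
    finding_sites = lapply(inst$finding_sites, function(s)
      s[c("surface_form", "start", "end", "snomed_code", "preferred_label")]),
    normalized = if (is.null(inst$normalized)) NULL else
      unclass(inst$normalized),
    values = as.list(inst$values),
    agreement = inst$agreement,
    equal_to_original = inst$equal_to_original,
    sentence_ref = inst$sentence_ref
  )
}

instance_from_list <- function(x, schema) {
  co <- x$concept
  inst <- new_instance(
    phenotype_concept(co$surface_form, co$start, co$end, co$snomed_code,
                      co$preferred_label),
    schema,
    sentence_ref = if (is.null(x$sentence_ref)) NULL else
      list(doc_id = x$sentence_ref$doc_id,
           sentence = if (is.null(x$sentence_ref$sentence)) NA_integer_
                      else as.integer(x$sentence_ref$sentence)))
  for (nm in names(x$values)) {
    inst <- set_attribute(inst, nm, x$values[[nm]], schema)
  }
  inst$finding_sites <- lapply(x$finding_sites, function(s)
    finding_site(s$surface_form, s$start, s$end, s$snomed_code,
                 s$preferred_label))
  if (!is.null(x$normalized)) {
    inst$normalized <- structure(
      list(kind = x$normalized$kind,
           phenotype_code = x$normalized$phenotype_code,
           site_codes = as.character(unlist(x$normalized$site_codes)),
           display = x$normalized$display),
      class = "normalized_expression")
  }
  if (!x$agreement %in% c("agree", "disagree")) stop("bad agreement flag")
  if (!x$equal_to_original %in% c("full", "partial")) stop("bad fidelity flag")
  inst$agreement <- x$agreement
  inst$equal_to_original <- x$equal_to_original
  inst
}

#' Serialize a knowledge graph to JSON
#'
#' @param graph A `phenossu_graph`.
#' @return A JSON string with stable field names; see [deserialize_graph()].
#' @export
serialize_graph <- function(graph) {
  stopifnot(inherits(graph, "phenossu_graph"))
  payload <- list(
    format = "phenossu_graph",
    disease_name = graph$disease_name,
    source_doc = graph$source_doc,
    instances = lapply(graph$instances, instance_to_list)
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                                digits = NA))
}

#' Deserialize a knowledge graph from JSON
#'
#' Inverse of [serialize_graph()]: round-trips all fields.
#'
#' @param text JSON string produced by [serialize_graph()].
#' @param schema The governing `phenossu_schema` (used to re-validate values).
#' @return A `phenossu_graph`.
#' @export
deserialize_graph <- function(text, schema) {
  payload <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                      error = function(e) stop("malformed graph payload: ",
                                               conditionMessage(e)))
  if (!identical(payload$format, "phenossu_graph")) {
    stop("malformed graph payload: missing format marker")
  }
  phenotype_graph(payload$disease_name, payload$source_doc,
                  lapply(payload$instances, instance_from_list,
                         schema = schema))
}
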