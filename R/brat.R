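# BRAT standoff annotation I/O: T (entity), A (attribute), R (relation)
# records over 0-based end-exclusive character offsets. Discontinuous spans
# ("s1 e1;s2 e2") are parsed and stored as multi-interval span tables; the
# entity text is the fragments joined with a single space, as BRAT emits.

new_standoff_document <- function(doc_id, text, entities = list(),
                                  attributes = list(), relations = list(),
                                  opaque = character()) {
  ids <- c(vapply(entities, `[[`, "", "id"),
           vapply(attributes, `[[`, "", "id"),
           vapply(relations, `[[`, "", "id"))
  if (anyDuplicated(ids)) {
    stop("duplicate annotation ids: ", paste(ids[duplicated(ids)],
                                             collapse = ", "))
  }
  ent_ids <- vapply(entities, `[[`, "", "id")
  for (a in attributes) {
    if (!a$target %in% ent_ids) {
      stop("reference error: attribute ", a$id,
           " targets missing entity ", a$target)
    }
  }
  for (r in relations) {
    if (!r$arg1 %in% ent_ids || !r$arg2 %in% ent_ids) {
      stop("reference error: relation ", r$id, " references a missing entity")
    }
  }
  names(entities) <- ent_ids
  structure(list(doc_id = doc_id, text = text, entities = entities,
                 attributes = attributes, relations = relations,
                 opaque = opaque),
            class = "standoff_document")
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document '%s': %d entities, %d attributes, %d relations>\n",
              x$doc_id, length(x$entities), length(x$attributes),
              length(x$relations)))
  invisible(x)
}

entity_envelope <- function(entity) {
  c(start = min(entity$spans$start), end = max(entity$spans$end))
}

span_signature <- function(spans) {
  paste(sprintf("%d-%d", spans$start, spans$end), collapse = ";")
}

#' Parse BRAT standoff annotation
#'
#' @param ann_content The `.ann` file content (one annotation per line).
#' @param doc_text The corresponding `.txt` document content.
#' @param doc_id Document identifier.
#' @return Object of class `standoff_document`. Entity texts are verified
#'   against the document (integrity error naming the offending line
#'   otherwise); attribute/relation references must resolve. Line types other
#'   than T/A/R are preserved as opaque records.
#' @export
parse_standoff <- function(ann_content, doc_text, doc_id = "doc") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  entities <- list(); attributes <- list(); relations <- list()
  opaque <- character()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- fields[1]
    if (grepl("^T[0-9]+$", id)) {
      if (length(fields) < 2L) stop("integrity error at line ", ln,
                                    ": malformed entity line")
      head_parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      type <- head_parts[1]
      span_str <- paste(head_parts[-1], collapse = " ")
      frags <- strsplit(span_str, ";", fixed = TRUE)[[1]]
      spans <- do.call(rbind, lapply(frags, function(f) {
        se <- as.integer(strsplit(trimws(f), " ", fixed = TRUE)[[1]])
        if (length(se) != 2L || anyNA(se)) {
          stop("integrity error at line ", ln, ": bad span '", f, "'")
        }
        data.frame(start = se[1], end = se[2])
      }))
      if (any(spans$start < 0L | spans$start >= spans$end |
                spans$end > nchar(doc_text))) {
        stop("integrity error at line ", ln, ": span outside document")
      }
      expected <- paste(mapply(function(s, e) span_text(doc_text, s, e),
                               spans$start, spans$end), collapse = " ")
      text <- if (length(fields) >= 3L) fields[3] else ""
      if (text != expected) {
        stop("integrity error at line ", ln, ": entity text '", text,
             "' does not match document substring '", expected, "'")
      }
      entities[[length(entities) + 1L]] <-
        list(id = id, type = type, spans = spans, text = text)
    } else if (grepl("^A[0-9]+$", id)) {
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("integrity error at line ", ln,
                                   ": malformed attribute line")
      attributes[[length(attributes) + 1L]] <-
        list(id = id, name = parts[1], target = parts[2],
             value = if (length(parts) >= 3L)
               paste(parts[-(1:2)], collapse = " ") else "")
    } else if (grepl("^R[0-9]+$", id)) {
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      args <- grep("^Arg[12]:", parts, value = TRUE)
      if (length(parts) < 3L || length(args) != 2L) {
        stop("integrity error at line ", ln, ": malformed relation line")
      }
      get_arg <- function(k) sub(paste0("^Arg", k, ":"), "",
                                 grep(paste0("^Arg", k, ":"), parts,
                                      value = TRUE)[1])
      relations[[length(relations) + 1L]] <-
        list(id = id, type = parts[1], arg1 = get_arg(1), arg2 = get_arg(2))
    } else {
      opaque <- c(opaque, line)
    }
  }
  new_standoff_document(doc_id, doc_text, entities, attributes, relations,
                        opaque)
}

#' Write BRAT standoff annotation
#'
#' Emits a canonical serialization: entity lines in numeric id order, then
#' attributes, then relations, then opaque records. The output re-parses to
#' an equivalent document.
#'
#' @param doc A `standoff_document`.
#' @return The `.ann` content as a single string ("" for an empty document).
#' @export
write_standoff <- function(doc) {
  stopifnot(inherits(doc, "standoff_document"))
  num <- function(ids) order(as.integer(sub("^[TAR]", "", ids)))
  ent <- doc$entities[num(vapply(doc$entities, `[[`, "", "id"))]
  att <- doc$attributes[num(vapply(doc$attributes, `[[`, "", "id"))]
  rel <- doc$relations[num(vapply(doc$relations, `[[`, "", "id"))]
  lines <- c(
    vapply(ent, function(e) {
      span_str <- paste(sprintf("%d %d", e$spans$start, e$spans$end),
                        collapse = ";")
      sprintf("%s\t%s %s\t%s", e$id, e$type, span_str, e$text)
    }, ""),
    vapply(att, function(a) {
      if (nzchar(a$value)) sprintf("%s\t%s %s %s", a$id, a$name, a$target,
                                   a$value)
      else sprintf("%s\t%s %s", a$id, a$name, a$target)
    }, ""),
    vapply(rel, function(r) sprintf("%s\t%s Arg1:%s Arg2:%s", r$id, r$type,
                                    r$arg1, r$arg2), ""),
    doc$opaque
  )
  paste(lines, collapse = "\n")
}

#' Generate BRAT configuration files for a schema
#'
#' Produces `annotation.conf` declaring the `Phenotype` and `FindingSite`
#' entity types, the `locate` relation, one attribute block per schema
#' attribute with its closed value set, and the two virtual attributes
#' (`agreement` for dual-annotation merging, `equal_to_original` for the
#' expressive-power judgment); plus a minimal `visual.conf`.
#'
#' @param schema A `phenossu_schema` (may have zero attributes, in which case
#'   only entities and relations are declared).
#' @return list(annotation_conf =, visual_conf =) of strings.
#' @export
generate_brat_config <- function(schema) {
  stopifnot(inherits(schema, "phenossu_schema"))
  attr_block <- character()
  if (length(schema$attributes)) {
    attr_block <- c(
      vapply(schema$attributes, function(a)
        sprintf("%s\tArg:Phenotype, Value:%s", a$name,
                paste(a$values$label, collapse = "|")), ""),
      "agreement\tArg:Phenotype, Value:agree|disagree",
      "equal_to_original\tArg:Phenotype, Value:full|partial")
  }
  annotation_conf <- paste(c(
    "[entities]", "Phenotype", "FindingSite", "",
    "[relations]", "locate\tArg1:Phenotype, Arg2:FindingSite", "",
    "[events]", "",
    "[attributes]", attr_block), collapse = "\n")
  visual_conf <- paste(c(
    "[labels]", "Phenotype | Phenotype | Phen",
    "FindingSite | Finding site | Site", "",
    "[drawing]",
    "Phenotype\tbgColor:#7fa2ff",
    "FindingSite\tbgColor:#9fe2a0"), collapse = "\n")
  list(annotation_conf = annotation_conf, visual_conf = visual_conf)
}

virtual_attribute_names <- c("agreement", "equal_to_original")

#' Convert a standoff document to phenotype instances
#'
#' One instance per `Phenotype` entity. `locate` relations populate the
#' finding sites, A-lines override the schema defaults (an A-line value
#' outside the attribute's value set is a closed-vocabulary error), and the
#' virtual `agreement` / `equal_to_original` attributes set the corresponding
#' flags. When a lexicon is supplied, concepts are SNOMED-normalized
#' (pre/postcoordinated with their sites).
#'
#' @param doc A `standoff_document`.
#' @param schema A `phenossu_schema`.
#' @param lexicon Optional `phenotype_lexicon` for concept normalization.
#' @param site_lexicon Optional `phenotype_lexicon` of body structures used
#'   to code finding sites.
#' @param precoordination_table Optional table from
#'   [load_precoordination_table()].
#' @return List of `phenossu_instance` objects, in entity order.
#' @export
to_instances <- function(doc, schema, lexicon = NULL, site_lexicon = NULL,
                         precoordination_table = NULL) {
  stopifnot(inherits(doc, "standoff_document"),
            inherits(schema, "phenossu_schema"))
  sents <- split_sentences(doc$text)
  sentence_index <- function(pos) {
    i <- which(sents$start <= pos & pos < sents$end)
    if (length(i)) i[1] else NA_integer_
  }
  attr_by_target <- split(doc$attributes,
                          vapply(doc$attributes, `[[`, "", "target"))
  out <- list()
  for (e in doc$entities) {
    if (e$type != "Phenotype") next
    env <- entity_envelope(e)
    discontinuous <- nrow(e$spans) > 1L
    code <- ""
    label <- e$text
    if (!is.null(lexicon)) {
      hit <- lexicon_lookup(lexicon, e$text)
      if (!is.null(hit)) { code <- hit$code; label <- hit$label }
    }
    concept <- phenotype_concept(
      e$text, env["start"], env["end"], code, label,
      doc_text = if (discontinuous) NULL else doc$text)
    inst <- new_instance(concept, schema,
                         sentence_ref = list(doc_id = doc$doc_id,
                                             sentence = sentence_index(env["start"])))
    inst$spans <- e$spans
    for (a in attr_by_target[[e$id]]) {
      if (a$name %in% virtual_attribute_names) {
        if (a$name == "agreement") inst$agreement <- a$value
        else inst$equal_to_original <- a$value
      } else {
        inst <- set_attribute(inst, a$name, a$value, schema)
      }
    }
    sites <- list()
    for (r in doc$relations) {
      if (r$type == "locate" && r$arg1 == e$id) {
        se <- doc$entities[[r$arg2]]
        if (is.null(se) || se$type != "FindingSite") next
        senv <- entity_envelope(se)
        scode <- ""
        slabel <- se$text
        if (!is.null(site_lexicon)) {
          shit <- lexicon_lookup(site_lexicon, se$text)
          if (!is.null(shit)) { scode <- shit$code; slabel <- shit$label }
        }
        sites[[length(sites) + 1L]] <-
          finding_site(se$text, senv["start"], senv["end"], scode, slabel)
      }
    }
    inst$finding_sites <- sites
    if (!is.null(lexicon) && nzchar(code)) {
      inst$normalized <- normalize_concept(concept, sites,
                                           precoordination_table, lexicon)
    }
    out[[length(out) + 1L]] <- inst
  }
  out
}

#' Build a standoff document from phenotype instances
#'
#' Inverse of [to_instances()]: emits one `Phenotype` entity per instance
#' with A-lines for its non-default attribute values (plus the virtual
#' attributes when they differ from their defaults), and `FindingSite`
#' entities connected by `locate` relations.
#'
#' @param instances List of `phenossu_instance` objects.
#' @param doc_id Document identifier.
#' @param text Document text the instance spans refer to.
#' @param schema A `phenossu_schema`.
#' @return A `standoff_document`.
#' @export
instances_to_standoff <- function(instances, doc_id, text, schema) {
  defaults <- schema_defaults(schema)
  entities <- list(); attributes <- list(); relations <- list()
  t_id <- 0L; a_id <- 0L; r_id <- 0L
  add_attr <- function(name, target, value) {
    a_id <<- a_id + 1L
    attributes[[length(attributes) + 1L]] <<-
      list(id = paste0("A", a_id), name = name, target = target,
           value = value)
  }
  for (inst in instances) {
    spans <- inst$spans %||% data.frame(start = inst$concept$start,
                                        end = inst$concept$end)
    t_id <- t_id + 1L
    eid <- paste0("T", t_id)
    entities[[length(entities) + 1L]] <-
      list(id = eid, type = "Phenotype", spans = spans,
           text = inst$concept$surface_form)
    for (nm in names(defaults)) {
      if (inst$values[[nm]] != defaults[[nm]]) {
        add_attr(nm, eid, inst$values[[nm]])
      }
    }
    if (inst$agreement != "agree") add_attr("agreement", eid,
                                            inst$agreement)
    if (inst$equal_to_original != "full") add_attr("equal_to_original", eid,
                                                   inst$equal_to_original)
    for (site in inst$finding_sites) {
      t_id <- t_id + 1L
      entities[[length(entities) + 1L]] <-
        list(id = paste0("T", t_id), type = "FindingSite",
             spans = data.frame(start = site$start, end = site$end),
             text = site$surface_form)
      r_id <- r_id + 1L
      relations[[length(relations) + 1L]] <-
        list(id = paste0("R", r_id), type = "locate", arg1 = eid,
             arg2 = paste0("T", t_id))
    }
  }
  new_standoff_document(doc_id, text, entities, attributes, relations)
}

#' Merge two independent annotations of the same document
#'
#' Two annotations of a phenotype are consistent iff their text spans are
#' identical and all attribute values match; every inconsistency (differing
#' values on the same span, or a span annotated by only one side) is marked
#' with the virtual attribute `agreement = disagree` in the merged document.
#' Span-overlapping but unequal annotations are kept as two disagreeing
#' entities.
#'
#' @param doc_a,doc_b `standoff_document`s over the same text.
#' @param schema A `phenossu_schema`.
#' @return A merged `standoff_document` containing the union of phenotype
#'   annotations with agreement marks; convert with [to_instances()] to
#'   inspect verdicts.
#' @export
merge_annotations <- function(doc_a, doc_b, schema) {
  if (!identical(doc_a$text, doc_b$text)) {
    stop("cannot merge annotations over differing document texts")
  }
  inst_a <- to_instances(doc_a, schema)
  inst_b <- to_instances(doc_b, schema)
  key <- function(inst) span_signature(inst$spans)
  keys_a <- vapply(inst_a, key, "")
  keys_b <- vapply(inst_b, key, "")
  all_keys <- union(keys_a, keys_b)
  defaults <- schema_defaults(schema)
  entities <- list(); attributes <- list()
  t_id <- 0L; a_id <- 0L
  add_attr <- function(name, target, value) {
    a_id <<- a_id + 1L
    attributes[[length(attributes) + 1L]] <<-
      list(id = paste0("A", a_id), name = name, target = target,
           value = value)
  }
  ord <- order(vapply(all_keys, function(k)
    min(c(inst_a[keys_a == k], inst_b[keys_b == k])[[1]]$concept$start), 0L))
  for (k in all_keys[ord]) {
    ia <- inst_a[keys_a == k]
    ib <- inst_b[keys_b == k]
    chosen <- if (length(ia)) ia[[1]] else ib[[1]]
    agree <- length(ia) > 0L && length(ib) > 0L &&
      identical(ia[[1]]$values[names(defaults)],
                ib[[1]]$values[names(defaults)])
    t_id <- t_id + 1L
    eid <- paste0("T", t_id)
    entities[[length(entities) + 1L]] <-
      list(id = eid, type = "Phenotype", spans = chosen$spans,
           text = chosen$concept$surface_form)
    for (nm in names(defaults)) {
      if (chosen$values[[nm]] != defaults[[nm]]) {
        add_attr(nm, eid, chosen$values[[nm]])
      }
    }
    add_attr("agreement", eid, if (agree) "agree" else "disagree")
  }
  new_standoff_document(paste0(doc_a$doc_id, "+", doc_b$doc_id), doc_a$text,
                        entities, attributes, list())
}
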