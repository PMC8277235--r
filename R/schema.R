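#' Load and validate an attribute schema
#'
#' The schema defines the closed set of attributes attached to every phenotype
#' instance: each attribute has a SNOMED-CT code, a category (`presence`,
#' `manifestation` or `spatial`), an ordered closed value set with per-value
#' SNOMED codes and trigger-term lexicons, and a default value. The default is
#' a schema-level sentinel (`present` for assertion, `none` elsewhere), not a
#' SNOMED annotation. The shipped configuration defines twelve attributes:
#' five presence, four manifestation and three spatial.
#'
#' @param path Path to a YAML schema configuration. Defaults to the
#'   configuration shipped with the package.
#' @return An object of class `phenossu_schema`: a list with `version` and
#'   `attributes`, the latter a named list of attribute definitions.
#' @examples
#' sch <- load_schema()
#' length(sch$attributes)
#' @export
load_schema <- function(path = phenossu_schema_path()) {
  if (!file.exists(path)) stop("schema config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes) || length(cfg$attributes) == 0L) {
    stop("schema config declares no attributes")
  }
  attrs <- lapply(cfg$attributes, parse_attribute_def)
  names(attrs) <- vapply(attrs, function(a) a$name, "")
  if (anyDuplicated(names(attrs))) {
    dup <- names(attrs)[duplicated(names(attrs))][1]
    stop("duplicate attribute name in schema: ", dup)
  }
  schema <- structure(
    list(version = as.character(cfg$version %||% "unversioned"),
         attributes = attrs),
    class = "phenossu_schema"
  )
  schema
}

parse_attribute_def <- function(a) {
  name <- a$name
  if (is.null(name) || !nzchar(name)) stop("schema attribute without a name")
  bad <- function(msg) stop("invalid schema attribute '", name, "': ", msg)
  if (is.null(a$category) ||
      !a$category %in% c("presence", "manifestation", "spatial")) {
    bad("category must be one of presence/manifestation/spatial")
  }
  if (is.null(a$values) || length(a$values) == 0L) bad("empty value set")
  labels <- vapply(a$values, function(v) as.character(v$label %||% ""), "")
  if (any(!nzchar(labels))) bad("a value is missing its label")
  if (anyDuplicated(labels)) bad("duplicate value labels")
  codes <- vapply(a$values, function(v) as.character(v$code %||% ""), "")
  if (any(nzchar(codes) & !grepl("^[0-9]+$", codes))) {
    bad("value codes must be strings of digits")
  }
  triggers <- lapply(a$values, function(v) {
    tr <- unlist(v$triggers, use.names = FALSE)
    if (is.null(tr)) character() else as.character(tr)
  })
  names(triggers) <- labels
  default <- as.character(a$default %||% "")
  if (!default %in% labels) {
    bad(sprintf("default value '%s' is not in the value set", default))
  }
  list(
    name = name,
    code = as.character(a$code %||% ""),
    category = a$category,
    default = default,
    values = data.frame(label = labels, code = codes,
                        stringsAsFactors = FALSE),
    triggers = triggers
  )
}

#' Path to the shipped schema configuration
#' @return File path of the default twelve-attribute YAML schema.
#' @export
phenossu_schema_path <- function() {
  system.file("extdata", "phenossu_schema.yaml", package = "phenossu",
              mustWork = TRUE)
}

#' @export
print.phenossu_schema <- function(x, ...) {
  cat(sprintf("<phenossu_schema v%s: %d attributes>\n", x$version,
              length(x$attributes)))
  for (a in x$attributes) {
    cat(sprintf("  %-18s [%s] default=%s values={%s}\n", a$name, a$category,
                a$default, paste(a$values$label, collapse = ", ")))
  }
  invisible(x)
}

#' Attribute names of a schema
#' @param schema A `phenossu_schema`.
#' @return Character vector of attribute names, in schema order.
#' @export
attribute_names <- function(schema) {
  stopifnot(inherits(schema, "phenossu_schema"))
  names(schema$attributes)
}

#' Look up one attribute definition
#' @param schema A `phenossu_schema`.
#' @param name Attribute name.
#' @return The attribute definition (a list).
#' @export
schema_attribute <- function(schema, name) {
  stopifnot(inherits(schema, "phenossu_schema"))
  a <- schema$attributes[[name]]
  if (is.null(a)) stop("unknown attribute: ", name)
  a
}

#' Default value assignment of a schema
#' @param schema A `phenossu_schema`.
#' @return Named character vector attribute -> default label.
#' @export
schema_defaults <- function(schema) {
  stopifnot(inherits(schema, "phenossu_schema"))
  vapply(schema$attributes, function(a) a$default, "")
}

# Flat trigger catalog: one row per (attribute, value, trigger term).
trigger_catalog <- function(schema) {
  rows <- list()
  for (a in schema$attributes) {
    for (lab in names(a$triggers)) {
      tr <- a$triggers[[lab]]
      if (length(tr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          attribute = a$name, value = lab, trigger = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(attribute = character(), value = character(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
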