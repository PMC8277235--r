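#' Load a precoordination table
#'
#' A precoordination table maps a (phenotype code, finding-site code) pair to
#' the single SNOMED-CT concept that expresses the composite meaning (e.g.
#' bleeding + nasal structure -> epistaxis). The table is a user-supplied
#' four-column TSV; an empty table is valid, in which case every composite
#' concept is postcoordinated.
#'
#' @param path TSV with columns phenotype_code, site_code, coordinated_code,
#'   coordinated_label. Defaults to the small table shipped with the package.
#' @return data.frame with those four character columns.
#' @export
load_precoordination_table <- function(path = system.file(
    "extdata", "precoordination.tsv", package = "phenossu", mustWork = TRUE)) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("phenotype_code", "site_code", "coordinated_code",
            "coordinated_label")
  if (!all(need %in% names(tab))) {
    stop("precoordination table must have columns: ",
         paste(need, collapse = ", "))
  }
  tab[need]
}

#' Normalize a phenotype concept together with its finding sites
#'
#' A phenotype with an associated finding site is treated as one integral
#' concept: if the (phenotype, site) pair has a precoordinated SNOMED-CT
#' concept it is normalized to that single code; otherwise phenotype and
#' site(s) are combined into a postcoordination expression. A phenotype
#' without sites normalizes to its own concept code.
#'
#' @param concept A [phenotype_concept()]; if its `snomed_code` is empty the
#'   surface form is resolved through `lexicon` when given.
#' @param sites List of [finding_site()] objects (possibly empty).
#' @param precoordination_table data.frame from
#'   [load_precoordination_table()], or NULL for none.
#' @param lexicon Optional `phenotype_lexicon` used to resolve an uncoded
#'   concept by its surface form.
#' @return Object of class `normalized_expression` with fields `kind`
#'   (`precoordinated`, `postcoordinated` or `concept_only`),
#'   `phenotype_code`, `site_codes` and a canonical `display` string.
#' @export
normalize_concept <- function(concept, sites = list(),
                              precoordination_table = NULL, lexicon = NULL) {
  stopifnot(inherits(concept, "phenotype_concept"))
  code <- concept$snomed_code
  label <- concept$preferred_label
  if (!nzchar(code) && !is.null(lexicon)) {
    hit <- lexicon_lookup(lexicon, concept$surface_form)
    if (!is.null(hit)) {
      code <- hit$code
      label <- hit$label
    }
  }
  if (!nzchar(code)) {
    stop("cannot normalize phenotype: no SNOMED code resolvable for '",
         concept$surface_form, "'")
  }
  pair_display <- function(cd, lb) paste0(cd, "|", lb)
  if (length(sites) == 1L && !is.null(precoordination_table) &&
      nrow(precoordination_table) > 0L) {
    hit <- precoordination_table[
      precoordination_table$phenotype_code == code &
        precoordination_table$site_code == sites[[1]]$snomed_code, ,
      drop = FALSE]
    if (nrow(hit) >= 1L) {
      return(structure(list(kind = "precoordinated",
                            phenotype_code = hit$coordinated_code[1],
                            site_codes = character(),
                            display = pair_display(hit$coordinated_code[1],
                                                   hit$coordinated_label[1])),
                       class = "normalized_expression"))
    }
  }
  if (length(sites) > 0L) {
    site_codes <- vapply(sites, function(s) s$snomed_code, "")
    site_disp <- vapply(sites, function(s)
      sprintf("\"%s\"", pair_display(s$snomed_code, s$preferred_label)), "")
    return(structure(list(kind = "postcoordinated",
                          phenotype_code = code,
                          site_codes = site_codes,
                          display = paste0("\"", pair_display(code, label),
                                           "\": ",
                                           paste(site_disp,
                                                 collapse = ", "))),
                     class = "normalized_expression"))
  }
  structure(list(kind = "concept_only", phenotype_code = code,
                 site_codes = character(),
                 display = pair_display(code, label)),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$kind, x$display))
  invisible(x)
}
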