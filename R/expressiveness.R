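#' Information-model profiles
#'
#' A profile is a named subset of schema attributes representing what a given
#' clinical information model can express about a phenotype; the empty subset
#' is the concept-only (phenotype-list) representation. Profiles drive the
#' expressive-power comparison in [compare_profiles()].
#'
#' @param name Profile name.
#' @param attribute_names Character vector of attribute names (may be empty).
#' @param schema A `phenossu_schema`; names are validated against it.
#' @return Object of class `model_profile`.
#' @export
model_profile <- function(name, attribute_names, schema) {
  attribute_names <- as.character(attribute_names)
  unknown <- setdiff(attribute_names, attribute_names(schema))
  if (length(unknown)) {
    stop("profile '", name, "' references unknown attribute(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(name = name, attribute_names = attribute_names),
            class = "model_profile")
}

#' Load model profiles from a YAML configuration
#'
#' @param path Profiles YAML (see the shipped `model_profiles.yaml`).
#' @param schema A `phenossu_schema`.
#' @return Named list of `model_profile` objects.
#' @export
load_profiles <- function(path = system.file("extdata",
                                             "model_profiles.yaml",
                                             package = "phenossu",
                                             mustWork = TRUE),
                          schema = load_schema()) {
  cfg <- yaml::read_yaml(path)
  profs <- lapply(cfg$profiles, function(p)
    model_profile(p$name, unlist(p$attributes), schema))
  stats::setNames(profs, vapply(profs, `[[`, "", "name"))
}

#' Can a profile precisely represent an instance?
#'
#' TRUE iff the gold annotation fully captures the original description
#' (`equal_to_original == "full"`) and every non-default attribute of the
#' instance is available in the profile. An all-default full-fidelity
#' instance is representable even by the concept-only profile.
#'
#' @param instance A `phenossu_instance`.
#' @param profile A `model_profile`.
#' @param schema A `phenossu_schema`.
#' @return Logical scalar.
#' @export
representable <- function(instance, profile, schema) {
  stopifnot(inherits(instance, "phenossu_instance"),
            inherits(profile, "model_profile"))
  if (instance$equal_to_original != "full") return(FALSE)
  defaults <- schema_defaults(schema)
  nondefault <- names(defaults)[instance$values[names(defaults)] != defaults]
  all(nondefault %in% profile$attribute_names)
}

#' Compare the expressive power of information-model profiles
#'
#' For each profile, counts the gold instances it can precisely represent
#' (see [representable()]) and reports the percentage. A profile whose
#' attribute set contains another's can never score lower.
#'
#' @param instances List of gold `phenossu_instance` objects.
#' @param profiles List of `model_profile` objects.
#' @param schema A `phenossu_schema`.
#' @return data.frame(profile, count_precise, total, percentage), percentages
#'   to one decimal place.
#' @export
compare_profiles <- function(instances, profiles, schema) {
  if (length(instances) == 0L) stop("no instances to compare")
  defaults <- schema_defaults(schema)
  full <- vapply(instances, function(x) x$equal_to_original == "full", NA)
  nondefault <- lapply(instances, function(x) {
    names(defaults)[x$values[names(defaults)] != defaults]
  })
  rows <- lapply(profiles, function(p) {
    ok <- full & vapply(nondefault, function(nd)
      all(nd %in% p$attribute_names), NA)
    data.frame(profile = p$name, count_precise = sum(ok),
               total = length(instances),
               percentage = round(100 * sum(ok) / length(instances), 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
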