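#' Model entities and their URI scheme
#'
#' A model entity addresses a variable or component of a CellML file. Its
#' canonical URI is the file path joined by `#` to the entity's
#' document-unique fragment, which is `component.variable` for variables and
#' plain `component` for component-level entities. The fragment is split at
#' the FIRST `.`: CellML component identifiers may not contain a dot, while
#' variable names in the wild occasionally do.
#'
#' @param model_file Relative path of the CellML file.
#' @param component Component identifier (non-empty).
#' @param variable Variable identifier, or `NULL` for a component-level
#'   entity.
#' @param metadata_id Document-unique metadata identifier; defaults to the
#'   URI fragment.
#' @return An object of class `model_entity`.
#' @examples
#' e <- model_entity("weinstein_1995.cellml", "NHE3", "J_NHE3_Na")
#' construct_entity_uri(e)
#' @export
model_entity <- function(model_file, component, variable = NULL, metadata_id = NULL) {
  if (is.null(model_file) || length(model_file) != 1L || !nzchar(model_file)) {
    abort_invalid_entity("model_file must be a non-empty string")
  }
  if (is.null(component) || length(component) != 1L || !nzchar(component)) {
    abort_invalid_entity("component must be a non-empty string")
  }
  if (!is.null(variable) && (length(variable) != 1L || !nzchar(variable))) {
    abort_invalid_entity("variable, when present, must be a non-empty string")
  }
  frag <- if (is.null(variable)) component else paste0(component, ".", variable)
  structure(
    list(model_file = model_file, component = component, variable = variable,
         metadata_id = if (is.null(metadata_id)) frag else metadata_id),
    class = "model_entity")
}

#' @export
print.model_entity <- function(x, ...) {
  cat("<", construct_entity_uri(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.model_entity <- function(x, ...) construct_entity_uri(x)

#' Construct the canonical URI of a model entity
#'
#' @param entity A [model_entity()].
#' @return The string `file#component.variable`, omitting `.variable` for a
#'   component-level entity. `parse_entity_uri()` inverts this exactly.
#' @export
construct_entity_uri <- function(entity) {
  if (!inherits(entity, "model_entity")) abort_invalid_entity("not a model_entity")
  frag <- if (is.null(entity$variable)) entity$component
          else paste0(entity$component, ".", entity$variable)
  paste0(entity$model_file, "#", frag)
}

#' Parse an entity URI into its parts
#'
#' Splits the URI at its single `#` into file and fragment, and the fragment
#' at the first `.` into component and variable.
#'
#' @param uri An entity URI such as `"weinstein_1995.cellml#NHE3.J_NHE3_Na"`.
#' @return A [model_entity()].
#' @export
parse_entity_uri <- function(uri) {
  if (length(uri) != 1L || is.na(uri)) abort_malformed_uri("entity URI must be a single string", uri)
  n_hash <- lengths(regmatches(uri, gregexpr("#", uri, fixed = TRUE)))
  if (n_hash != 1L) {
    abort_malformed_uri(paste0("entity URI must contain exactly one '#': '", uri, "'"), uri)
  }
  parts <- strsplit(uri, "#", fixed = TRUE)[[1]]
  file <- parts[1]
  frag <- if (length(parts) < 2L) "" else parts[2]
  if (!nzchar(file)) abort_malformed_uri(paste0("empty file part in '", uri, "'"), uri)
  if (!nzchar(frag)) abort_malformed_uri(paste0("empty fragment in '", uri, "'"), uri)
  dot <- regexpr(".", frag, fixed = TRUE)
  if (dot == -1L) {
    model_entity(file, frag)
  } else {
    comp <- substr(frag, 1L, dot - 1L)
    var <- substr(frag, dot + 1L, nchar(frag))
    if (!nzchar(comp) || !nzchar(var)) {
      abort_malformed_uri(paste0("fragment has empty component or variable: '", uri, "'"), uri)
    }
    model_entity(file, comp, var)
  }
}

is_entity_uri <- function(uri) {
  lengths(regmatches(uri, gregexpr("#", uri, fixed = TRUE))) == 1L &
    !startsWith(uri, "#") & !endsWith(uri, "#")
}
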