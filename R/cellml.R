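CELLML_1_0_NS <- "http://www.cellml.org/cellml/1.0#"
CELLML_1_1_NS <- "http://www.cellml.org/cellml/1.1#"
CELLML_2_0_NS <- "http://www.cellml.org/cellml/2.0#"
CMETA_NS <- "http://www.cellml.org/metadata/1.0#"

#' Parse a CellML model file
#'
#' Reads a CellML 1.0 or 1.1 document and returns its components and
#' variables together with their document-unique metadata identifiers
#' (`cmeta:id`). Mathematics (MathML) is not interpreted; CellML 2.0 uses a
#' different metadata mechanism and is rejected explicitly rather than
#' silently mis-parsed.
#'
#' @param path Path to the `.cellml` file.
#' @return An object of class `cellml_model` with fields `file`, `name`,
#'   `components` (data.frame: name, metadata_id) and `variables`
#'   (data.frame: component, name, metadata_id, units).
#' @export
read_cellml <- function(path) {
  if (!file.exists(path)) abort_not_found(paste0("no such file: ", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_parse(
                    paste0("malformed XML in '", path, "': ", conditionMessage(e)),
                    file = path))
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(root)
  model_ns <- node_ns_of_root(root)
  if (identical(model_ns, CELLML_2_0_NS)) {
    semdisc_error(paste0("CellML 2.0 documents are not supported (found namespace ",
                         model_ns, ")"), "semdisc_unsupported_dialect")
  }
  if (!model_ns %in% c(CELLML_1_0_NS, CELLML_1_1_NS)) {
    semdisc_error(paste0("not a CellML 1.0/1.1 document: root namespace is '",
                         model_ns, "'"), "semdisc_unsupported_dialect")
  }
  ns <- c(c = model_ns, cmeta = CMETA_NS)
  name <- xml2::xml_attr(root, "name")
  comp_nodes <- xml2::xml_find_all(root, "./c:component", ns)
  components <- data.frame(
    name = xml2::xml_attr(comp_nodes, "name"),
    metadata_id = xml2::xml_attr(comp_nodes, "id"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(components$name)) {
    abort_parse(paste0("duplicate component names in '", path, "'"), file = path)
  }
  vars <- do.call(rbind, lapply(comp_nodes, function(cn) {
    vn <- xml2::xml_find_all(cn, "./c:variable", ns)
    if (length(vn) == 0L) return(NULL)
    data.frame(component = xml2::xml_attr(cn, "name"),
               name = xml2::xml_attr(vn, "name"),
               metadata_id = xml2::xml_attr(vn, "id"),
               units = xml2::xml_attr(vn, "units"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(vars)) {
    vars <- data.frame(component = character(), name = character(),
                       metadata_id = character(), units = character(),
                       stringsAsFactors = FALSE)
  }
  dup <- duplicated(paste(vars$component, vars$name))
  if (any(dup)) abort_parse(paste0("duplicate variable names within a component in '", path, "'"),
                            file = path)
  ids <- c(components$metadata_id, vars$metadata_id)
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids)) {
    abort_parse(paste0("metadata identifiers are not document-unique in '", path, "'"),
                file = path)
  }
  structure(list(file = basename(path), path = path,
                 name = if (is.na(name)) basename(path) else name,
                 components = components, variables = vars),
            class = "cellml_model")
}

node_ns_of_root <- function(root) {
  doc_ns <- xml2::xml_ns(root)
  qname <- xml2::xml_name(root, ns = doc_ns)
  if (grepl(":", qname, fixed = TRUE)) {
    pfx <- sub(":.*$", "", qname)
    uri <- unname(doc_ns[names(doc_ns) == pfx])
    if (length(uri) == 1L) return(uri)
  }
  ""
}

#' @export
print.cellml_model <- function(x, ...) {
  cat("CellML model '", x$name, "': ", nrow(x$components), " components, ",
      nrow(x$variables), " variables\n", sep = "")
  invisible(x)
}

#' Extract the RDF metadata block embedded in a CellML file
#'
#' CellML documents may carry annotations in an in-file `rdf:RDF` block whose
#' subjects reference metadata identifiers as `#id` fragments; these are
#' resolved against the model's file name so that subjects become canonical
#' entity URIs.
#'
#' @param path Path to the CellML file.
#' @param base Base URI for `#fragment` resolution; defaults to the file
#'   name.
#' @return An [rdf_triples()] table (empty if the file has no RDF block).
#' @export
read_cellml_rdf <- function(path, base = basename(path)) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_parse(
                    paste0("malformed XML in '", path, "': ", conditionMessage(e)),
                    file = path))
  hits <- xml2::xml_find_all(doc, ".//rdf:RDF", ns = c(rdf = RDF_NS))
  if (length(hits) == 0L) return(empty_triples())
  parts <- lapply(hits, function(h) rdfxml_triples(h, base = base))
  rename_blanks(dedupe_triples(do.call(triples_rbind, parts)), "m")
}

#' All entities of a parsed model, as a data.frame of canonical URIs
#' @param model A `cellml_model`.
#' @return data.frame with columns uri, file, component, variable.
#' @export
model_entities <- function(model) {
  comp <- data.frame(uri = paste0(model$file, "#", model$components$name),
                     file = model$file, component = model$components$name,
                     variable = NA_character_, stringsAsFactors = FALSE)
  if (nrow(model$variables) > 0L) {
    var <- data.frame(
      uri = paste0(model$file, "#", model$variables$component, ".", model$variables$name),
      file = model$file, component = model$variables$component,
      variable = model$variables$name, stringsAsFactors = FALSE)
  } else var <- NULL
  out <- rbind(comp, var)
  rownames(out) <- NULL
  out
}
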