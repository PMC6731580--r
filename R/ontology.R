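#' Ontology terms and the prefix registry
#'
#' An ontology term is a reference-ontology concept: an absolute IRI, a short
#' prefix naming the ontology it comes from (OPB, FMA, CHEBI, PR, GO, UNIPROT,
#' or OTHER for anything unrecognised), and an optional human-readable label.
#' The prefix is derived from the IRI through a configurable prefix registry
#' mapping IRI stems to prefixes; it is never stored independently of the IRI.
#' Two terms are equal exactly when their IRIs are equal (after trimming
#' surrounding whitespace; ontology IRIs are case-sensitive, so no case
#' folding is applied).
#'
#' @param uri Absolute IRI of the concept.
#' @param label Optional human-readable label.
#' @param registry Prefix registry as returned by [read_prefix_registry()];
#'   defaults to the registry shipped with the package.
#' @return An object of class `ontology_term` with fields `uri`, `prefix`,
#'   `label`.
#' @examples
#' ontology_term("https://identifiers.org/CHEBI:29101", label = "sodium")
#' @export
ontology_term <- function(uri, label = NULL, registry = default_prefix_registry()) {
  if (length(uri) != 1L || is.na(uri)) abort_invalid_input("term URI must be a single string")
  uri <- trimws(uri)
  if (!nzchar(uri)) abort_invalid_input("term URI must be non-empty")
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", uri)) {
    abort_malformed_uri(paste0("not an absolute IRI: '", uri, "'"), uri = uri)
  }
  structure(
    list(uri = uri,
         prefix = prefix_for_uri(uri, registry),
         label = if (is.null(label) || is.na(label)) NULL else as.character(label)),
    class = "ontology_term")
}

#' @export
print.ontology_term <- function(x, ...) {
  cat("<", x$uri, "> [", x$prefix, "]",
      if (!is.null(x$label)) paste0(" \"", x$label, "\""), "\n", sep = "")
  invisible(x)
}

#' @export
`==.ontology_term` <- function(e1, e2) {
  identical(term_uri(e1), term_uri(e2))
}

term_uri <- function(x) if (inherits(x, "ontology_term")) x$uri else as.character(x)

term_label <- function(x) if (inherits(x, "ontology_term")) x$label else NULL

is_term <- function(x) inherits(x, "ontology_term")

#' Read a prefix registry file
#'
#' The registry is a flat two-column text file, one record per line:
#' `prefix<TAB>uri-stem`. Lines starting with `#` are comments. A term IRI is
#' classified by the longest stem that prefixes it; IRIs matching no stem
#' classify as `OTHER`.
#'
#' @param path Path to the registry file.
#' @return A data.frame with columns `prefix` and `stem`.
#' @export
read_prefix_registry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.frame(prefix = character(), stem = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) abort_parse(paste0("malformed registry line: '", lines[bad][1], "'"), file = path)
  data.frame(prefix = vapply(parts, `[[`, "", 1L),
             stem = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Default prefix registry
#'
#' Covers the reference ontologies the annotation model uses (OPB, FMA, ChEBI,
#' PR, GO, UniProt) under their common IRI stems, plus the reserved
#' example.org stems used by the synthetic fixture corpus so that fixture
#' terms classify like real ones without ever colliding with real IDs.
#'
#' @return A data.frame with columns `prefix` and `stem`.
#' @export
default_prefix_registry <- function() {
  reg <- getOption("semdisc.prefix_registry")
  if (!is.null(reg)) return(reg)
  path <- system.file("extdata", "prefixes.tsv", package = "semdisc")
  if (nzchar(path)) read_prefix_registry(path) else builtin_prefix_registry()
}

builtin_prefix_registry <- function() {
  data.frame(
    prefix = c("OPB", "OPB", "FMA", "FMA", "CHEBI", "CHEBI", "PR", "PR",
               "GO", "UNIPROT", "UNIPROT",
               "OPB", "FMA", "CHEBI", "PR", "UNIPROT"),
    stem = c("http://bhi.washington.edu/OPB#",
             "http://identifiers.org/opb/",
             "http://purl.org/sig/ont/fma/",
             "http://identifiers.org/fma/",
             "http://purl.obolibrary.org/obo/CHEBI_",
             "https://identifiers.org/CHEBI:",
             "http://purl.obolibrary.org/obo/PR_",
             "https://identifiers.org/pr/",
             "http://purl.obolibrary.org/obo/GO_",
             "http://identifiers.org/uniprot/",
             "https://www.uniprot.org/uniprot/",
             "https://example.org/onto/OPB_",
             "https://example.org/onto/FMA_",
             "https://example.org/onto/CHEBI_",
             "https://example.org/onto/PR_",
             "https://example.org/protein/"),
    stringsAsFactors = FALSE)
}

prefix_for_uri <- function(uri, registry) {
  hits <- registry[startsWith(uri, registry$stem), , drop = FALSE]
  if (nrow(hits) == 0L) return("OTHER")
  hits$prefix[which.max(nchar(hits$stem))]
}
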