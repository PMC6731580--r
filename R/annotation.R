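#' Composite annotations
#'
#' A composite annotation binds one model entity to a machine-readable
#' description assembled from several reference ontologies: a mandatory
#' biophysical property (OPB, e.g. chemical flow or concentration), an
#' optional chemical species (ChEBI), anatomical locations (FMA), and an
#' optional protein mediator (PR or UniProt). Process-type properties such as
#' fluxes carry `source_location` / `sink_location` chains (most specific
#' term first); state-type properties such as concentrations carry a
#' `located_in` chain instead. Species and gene are free-text strings, since
#' they are displayed as plain text columns, not ontology terms.
#'
#' @param target A [model_entity()] the annotation describes.
#' @param property The biophysical property term (mandatory).
#' @param chemical Optional chemical species term.
#' @param source_location,sink_location Lists of location terms for
#'   process-type annotations, most specific first.
#' @param located_in List of location terms for state-type annotations.
#' @param mediator Optional protein mediator term.
#' @param species,gene Optional free-text species / gene names.
#' @return An object of class `composite_annotation`.
#' @export
composite_annotation <- function(target, property, chemical = NULL,
                                 source_location = list(), sink_location = list(),
                                 located_in = list(), mediator = NULL,
                                 species = NULL, gene = NULL) {
  if (!inherits(target, "model_entity")) abort_invalid_input("target must be a model_entity")
  if (!is_term(property)) abort_invalid_input("property term is mandatory")
  if (!is.null(chemical) && !is_term(chemical)) abort_invalid_input("chemical must be an ontology_term")
  if (!is.null(mediator) && !is_term(mediator)) abort_invalid_input("mediator must be an ontology_term")
  source_location <- as_term_chain(source_location, "source_location")
  sink_location <- as_term_chain(sink_location, "sink_location")
  located_in <- as_term_chain(located_in, "located_in")
  if ((length(source_location) > 0L || length(sink_location) > 0L) && length(located_in) > 0L) {
    abort_invalid_input("an annotation uses either source/sink locations (process) or located_in (state), not both")
  }
  structure(
    list(target = target, property = property, chemical = chemical,
         source_location = source_location, sink_location = sink_location,
         located_in = located_in, mediator = mediator,
         species = scalar_or_null(species), gene = scalar_or_null(gene)),
    class = "composite_annotation")
}

scalar_or_null <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1]) || !nzchar(x[1])) NULL else as.character(x[1])
}

as_term_chain <- function(x, what) {
  if (is_term(x)) x <- list(x)
  if (!is.list(x)) abort_invalid_input(paste0(what, " must be a list of ontology_term"))
  if (!all(vapply(x, is_term, TRUE))) abort_invalid_input(paste0(what, " must contain only ontology_term objects"))
  uris <- vapply(x, term_uri, "")
  if (anyDuplicated(uris)) abort_invalid_input(paste0(what, " chain contains duplicate terms"))
  x
}

#' @export
print.composite_annotation <- function(x, ...) {
  cat("composite annotation on <", construct_entity_uri(x$target), ">\n", sep = "")
  desc <- tryCatch(render_description(x), semdisc_error = function(e) NULL)
  if (!is.null(desc)) cat("  ", desc, "\n", sep = "")
  invisible(x)
}

annotation_is_process <- function(a) {
  length(a$source_location) > 0L || length(a$sink_location) > 0L
}

#' All location terms used by an annotation (source, sink and located_in)
#' @keywords internal
annotation_location_terms <- function(a) {
  c(a$source_location, a$sink_location, a$located_in)
}

resolve_label <- function(term, labels = NULL) {
  lbl <- term_label(term)
  if (!is.null(lbl)) return(lbl)
  if (!is.null(labels)) {
    hit <- tryCatch(label_for(term_uri(term), labels), semdisc_error = function(e) NULL)
    if (!is.null(hit)) return(hit)
  }
  abort_unresolved_label(term_uri(term))
}

#' Render an annotation as human-readable text
#'
#' Deterministic template expansion. Process-type annotations (those with
#' source or sink locations) render as
#' `"<chemical> <property> from <source> to <sink> via <mediator>"`;
#' state-type annotations render as `"<chemical> <property> in <location>"`.
#' Absent optional slots collapse grammatically, so there is never a dangling
#' `"via"`, `"from"` or `"in"`. Location chains contribute their most
#' specific (first) term's label.
#'
#' @param a A [composite_annotation()].
#' @param labels Optional [label_cache()] consulted for terms that carry no
#'   inline label.
#' @return A single string, e.g. `"sodium flux from proximal tubule to
#'   epithelial cell cytosol via sodium/hydrogen exchanger 3"`.
#' @export
render_description <- function(a, labels = NULL) {
  if (!inherits(a, "composite_annotation")) abort_invalid_input("not a composite_annotation")
  lab <- function(term) resolve_label(term, labels)
  head_words <- c(if (!is.null(a$chemical)) lab(a$chemical), lab(a$property))
  out <- paste(head_words, collapse = " ")
  if (annotation_is_process(a)) {
    if (length(a$source_location) > 0L) out <- paste(out, "from", lab(a$source_location[[1]]))
    if (length(a$sink_location) > 0L) out <- paste(out, "to", lab(a$sink_location[[1]]))
    if (!is.null(a$mediator)) out <- paste(out, "via", lab(a$mediator))
  } else {
    if (length(a$located_in) > 0L) out <- paste(out, "in", lab(a$located_in[[1]]))
    if (!is.null(a$mediator)) out <- paste(out, "via", lab(a$mediator))
  }
  out
}

#' Annotated corpora
#'
#' An annotated corpus bundles a set of model descriptors with the composite
#' annotations attached to their entities, plus two lookup indexes: entity
#' URI to annotation, and ontology-term URI to the entities it annotates
#' (tagged with the slot the term fills). The indexes are derived data,
#' rebuildable from the annotation list to identical content.
#'
#' @param models A data.frame with columns `file` and `name`, one row per
#'   model.
#' @param annotations A list of [composite_annotation()] objects.
#' @param entities Optional data.frame of all known entities (columns `uri`,
#'   `file`, `component`, `variable`); entities of annotations are added
#'   automatically. Unannotated entities are retained.
#' @return An object of class `annotated_corpus`.
#' @export
annotated_corpus <- function(models, annotations = list(), entities = NULL) {
  models <- as.data.frame(models, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "name") %in% names(models)))
  ann_files <- vapply(annotations, function(a) a$target$model_file, "")
  missing <- setdiff(ann_files, models$file)
  if (length(missing) > 0L) {
    abort_invalid_input(paste0("annotation targets reference models absent from the corpus: ",
                               paste(missing, collapse = ", ")))
  }
  ent <- data.frame(uri = character(), file = character(), component = character(),
                    variable = character(), stringsAsFactors = FALSE)
  if (!is.null(entities) && nrow(as.data.frame(entities)) > 0L) {
    ent <- as.data.frame(entities, stringsAsFactors = FALSE)[, c("uri", "file", "component", "variable")]
  }
  ann_ent <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(uri = construct_entity_uri(a$target), file = a$target$model_file,
               component = a$target$component,
               variable = if (is.null(a$target$variable)) NA_character_ else a$target$variable,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ann_ent)) ent <- rbind(ent, ann_ent[!ann_ent$uri %in% ent$uri, , drop = FALSE])
  ent <- ent[!duplicated(ent$uri), , drop = FALSE]
  ent <- ent[order(ent$uri), , drop = FALSE]
  rownames(ent) <- NULL
  corpus <- structure(
    list(models = models[order(models$file), , drop = FALSE],
         entities = ent, annotations = annotations,
         index = NULL),
    class = "annotated_corpus")
  corpus$index <- build_corpus_index(annotations)
  corpus
}

#' Rebuild the corpus lookup indexes from its annotation set
#'
#' @param annotations List of composite annotations.
#' @return A list with `by_entity` (entity URI -> annotation) and `by_term`
#'   (data.frame term URI / entity URI / slot).
#' @export
build_corpus_index <- function(annotations) {
  by_entity <- list()
  rows <- list()
  for (a in annotations) {
    uri <- construct_entity_uri(a$target)
    by_entity[[uri]] <- a
    add <- function(term, slot) {
      rows[[length(rows) + 1L]] <<- data.frame(
        term = term_uri(term), entity = uri, slot = slot, stringsAsFactors = FALSE)
    }
    add(a$property, "property")
    if (!is.null(a$chemical)) add(a$chemical, "chemical")
    for (t in annotation_location_terms(a)) add(t, "location")
    if (!is.null(a$mediator)) add(a$mediator, "mediator")
  }
  by_term <- if (length(rows) == 0L) {
    data.frame(term = character(), entity = character(), slot = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  by_term <- unique(by_term)
  by_term <- by_term[order(by_term$term, by_term$entity, by_term$slot), , drop = FALSE]
  rownames(by_term) <- NULL
  list(by_entity = by_entity, by_term = by_term)
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat("annotated corpus:", nrow(x$models), "models,", nrow(x$entities), "entities,",
      length(x$annotations), "annotations\n")
  invisible(x)
}

corpus_annotation_for <- function(corpus, uri) corpus$index$by_entity[[uri]]

#' Retrieve every label carried by a corpus's terms as a label cache
#' @param corpus An [annotated_corpus()].
#' @return A [label_cache()] populated from the annotation terms.
#' @export
corpus_labels <- function(corpus) {
  cache <- label_cache()
  for (a in corpus$annotations) {
    for (t in c(list(a$property), if (!is.null(a$chemical)) list(a$chemical),
                annotation_location_terms(a),
                if (!is.null(a$mediator)) list(a$mediator))) {
      if (!is.null(term_label(t))) label_put(cache, term_uri(t), term_label(t))
    }
  }
  cache
}
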