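# Workspace ingestion: scan a directory for CellML models and RDF
# annotation documents, merge in-file and sibling annotations (sibling
# documents take precedence per entity, the workspace-style layout), and
# assemble the annotated corpus plus its triple store.

#' Ingest a workspace directory into an annotated corpus
#'
#' Annotations may live inside each CellML file's RDF block or in sibling
#' RDF documents (`.ttl`, `.rdf`) in the same directory; both are scanned.
#' When both define an annotation for the same entity, the sibling
#' document's version wins.
#'
#' @param dir Directory containing CellML and/or RDF documents.
#' @param vocabulary Annotation predicate vocabulary.
#' @return An [annotated_corpus()] whose `store` element is a
#'   [triple_store()] over all ingested triples.
#' @export
ingest_corpus <- function(dir, vocabulary = default_vocabulary()) {
  if (!dir.exists(dir)) abort_not_found(paste0("no such directory: ", dir))
  cellml_files <- sort(list.files(dir, pattern = "\\.cellml$", full.names = TRUE))
  rdf_files <- sort(list.files(dir, pattern = "\\.(ttl|rdf)$", full.names = TRUE))
  if (length(cellml_files) == 0L && length(rdf_files) == 0L) {
    abort_invalid_input(paste0("no CellML or RDF documents found in: ", dir))
  }
  models <- list()
  infile_parts <- list()
  for (path in cellml_files) {
    model <- tryCatch(read_cellml(path), semdisc_error = function(e) {
      semdisc_warning(paste0("skipping unparseable model '", basename(path), "': ",
                             conditionMessage(e)), "semdisc_ingest_warning")
      NULL
    })
    if (is.null(model)) next
    models[[length(models) + 1L]] <- model
    infile_parts[[length(infile_parts) + 1L]] <- read_cellml_rdf(path)
  }
  if (length(models) == 0L) {
    abort_invalid_input(paste0("no parseable CellML models in: ", dir))
  }
  infile_triples <- dedupe_triples(do.call(triples_rbind, c(list(empty_triples()), infile_parts)))
  sibling_triples <- if (length(rdf_files) > 0L) {
    read_annotation_graph(rdf_files)
  } else empty_triples()

  corpus_sib <- extract_annotations(models, sibling_triples, vocabulary)
  corpus_inf <- extract_annotations(models, infile_triples, vocabulary)
  sib_uris <- names(corpus_sib$index$by_entity)
  merged <- c(corpus_sib$annotations,
              Filter(function(a) !construct_entity_uri(a$target) %in% sib_uris,
                     corpus_inf$annotations))
  model_df <- corpus_sib$models
  # prefer sibling-derived titles, fall back to in-file ones
  for (i in seq_len(nrow(model_df))) {
    if (model_df$name[i] == model_df$file[i]) {
      model_df$name[i] <- corpus_inf$models$name[match(model_df$file[i], corpus_inf$models$file)]
    }
  }
  corpus <- annotated_corpus(model_df, merged,
                             entities = do.call(rbind, lapply(models, model_entities)))
  corpus$store <- triple_store(triples_rbind(infile_triples, sibling_triples))
  corpus$dir <- dir
  corpus
}

#' Summarize an ingested corpus
#' @param corpus An [annotated_corpus()].
#' @return A named list of counts: models, components, variables, entities,
#'   annotations.
#' @export
corpus_summary <- function(corpus) {
  list(models = nrow(corpus$models),
       components = sum(is.na(corpus$entities$variable)),
       variables = sum(!is.na(corpus$entities$variable)),
       entities = nrow(corpus$entities),
       annotations = length(corpus$annotations))
}

#' Persist the corpus annotation index as a canonical Turtle document
#'
#' Re-running ingest and export on unchanged inputs yields a byte-identical
#' index document.
#'
#' @param corpus An [annotated_corpus()].
#' @param path Output path (default `corpus_index.ttl` under the corpus
#'   directory).
#' @export
export_corpus_index <- function(corpus, path = file.path(corpus$dir %||% ".", "corpus_index.ttl")) {
  write_annotation_graph(encode_annotations(corpus), path, dialect = "turtle")
  invisible(path)
}
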