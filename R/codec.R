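# Codec between composite annotations and RDF triples. The relation
# vocabulary (predicate IRIs for property / chemical / source / sink /
# mediator / located-in) is fixed in one vocabulary table so that a
# different annotation dialect is a configuration change, not a code change.

SEMSIM_NS <- "http://bhi.washington.edu/SemSim#"
DCTERMS_NS <- "http://purl.org/dc/terms/"

default_vocabulary <- function() {
  voc <- getOption("semdisc.vocabulary")
  if (!is.null(voc)) return(voc)
  path <- system.file("extdata", "vocabulary.tsv", package = "semdisc")
  if (nzchar(path)) read_vocabulary(path) else builtin_vocabulary()
}

builtin_vocabulary <- function() {
  c(property = paste0(SEMSIM_NS, "hasPhysicalProperty"),
    chemical = paste0(SEMSIM_NS, "hasPhysicalEntity"),
    source = paste0(SEMSIM_NS, "hasSourceParticipant"),
    sink = paste0(SEMSIM_NS, "hasSinkParticipant"),
    located_in = paste0(SEMSIM_NS, "isLocatedIn"),
    mediator = paste0(SEMSIM_NS, "hasMediatorParticipant"),
    refers_to = paste0(SEMSIM_NS, "refersTo"),
    part_of = paste0(SEMSIM_NS, "partOf"),
    species = paste0(SEMSIM_NS, "hasSpecies"),
    gene = paste0(SEMSIM_NS, "hasGene"),
    model_title = paste0(DCTERMS_NS, "title"),
    label = paste0(RDFS_NS, "label"))
}

#' Read an annotation vocabulary file
#'
#' Two tab-separated columns, `slot<TAB>predicate-iri`; `#` comments. The
#' slots `property`, `chemical`, `source`, `sink`, `located_in`, `mediator`,
#' `refers_to`, `part_of`, `species`, `gene`, `model_title` and `label` must
#' all be present.
#'
#' @param path Path to the vocabulary file.
#' @return A named character vector of predicate IRIs.
#' @export
read_vocabulary <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  voc <- setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
  needed <- names(builtin_vocabulary())
  missing <- setdiff(needed, names(voc))
  if (length(missing) > 0L) {
    abort_parse(paste0("vocabulary file lacks slots: ", paste(missing, collapse = ", ")),
                file = path)
  }
  voc
}

# --- encoding --------------------------------------------------------------

encode_term_label <- function(term) {
  if (is.null(term_label(term))) return(NULL)
  list(s = term_uri(term), o = term_label(term))
}

#' Encode composite annotations as RDF triples
#'
#' Location chains are encoded as linked participant nodes: the entity points
#' to a blank node that `refersTo` the most specific location term and is
#' `partOf` the next node in the chain. Term labels are emitted as
#' `rdfs:label` statements so that a corpus round-trips with its
#' human-readable vocabulary intact.
#'
#' @param annotations List of [composite_annotation()] objects (or an
#'   [annotated_corpus()], whose model titles are then included).
#' @param vocabulary Predicate vocabulary, defaulting to the packaged one.
#' @return An [rdf_triples()] table.
#' @export
encode_annotations <- function(annotations, vocabulary = default_vocabulary()) {
  models <- NULL
  if (inherits(annotations, "annotated_corpus")) {
    models <- annotations$models
    annotations <- annotations$annotations
  }
  voc <- vocabulary
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  s <- character(); p <- character(); o <- character()
  o_type <- character()
  emit <- function(su, pr, ob, ty) {
    s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob); o_type <<- c(o_type, ty)
  }
  labels <- list()
  note_label <- function(term) {
    if (!is.null(term_label(term))) labels[[term_uri(term)]] <<- term_label(term)
  }
  emit_chain <- function(subject, pred, chain) {
    if (length(chain) == 0L) return(invisible())
    nodes <- vapply(seq_along(chain), function(i) {
      counter$n <- counter$n + 1L
      paste0("_:n", counter$n)
    }, "")
    emit(subject, pred, nodes[1], "blank")
    for (i in seq_along(chain)) {
      emit(nodes[i], voc[["refers_to"]], term_uri(chain[[i]]), "iri")
      note_label(chain[[i]])
      if (i < length(chain)) emit(nodes[i], voc[["part_of"]], nodes[i + 1L], "blank")
    }
  }
  for (a in annotations) {
    uri <- construct_entity_uri(a$target)
    emit(uri, voc[["property"]], term_uri(a$property), "iri"); note_label(a$property)
    if (!is.null(a$chemical)) {
      emit(uri, voc[["chemical"]], term_uri(a$chemical), "iri"); note_label(a$chemical)
    }
    emit_chain(uri, voc[["source"]], a$source_location)
    emit_chain(uri, voc[["sink"]], a$sink_location)
    emit_chain(uri, voc[["located_in"]], a$located_in)
    if (!is.null(a$mediator)) {
      emit(uri, voc[["mediator"]], term_uri(a$mediator), "iri"); note_label(a$mediator)
    }
    if (!is.null(a$species)) emit(uri, voc[["species"]], a$species, "literal")
    if (!is.null(a$gene)) emit(uri, voc[["gene"]], a$gene, "literal")
  }
  for (u in names(labels)) emit(u, voc[["label"]], labels[[u]], "literal")
  if (!is.null(models)) {
    for (i in seq_len(nrow(models))) {
      emit(models$file[i], voc[["model_title"]], models$name[i], "literal")
    }
  }
  dedupe_triples(rdf_triples(s, p, o, o_type))
}

# --- decoding --------------------------------------------------------------

objects_of <- function(df, subject, predicate) {
  df[df$s == subject & df$p == predicate, , drop = FALSE]
}

decode_term <- function(df, uri, voc) {
  lab <- objects_of(df, uri, voc[["label"]])
  ontology_term(uri, label = if (nrow(lab) > 0L) lab$o[1] else NULL)
}

decode_chain <- function(df, head_node, voc, seen = character()) {
  if (head_node %in% seen) return(list())
  ref <- objects_of(df, head_node, voc[["refers_to"]])
  if (nrow(ref) == 0L) return(list())
  term <- decode_term(df, ref$o[1], voc)
  nxt <- objects_of(df, head_node, voc[["part_of"]])
  rest <- if (nrow(nxt) > 0L) decode_chain(df, nxt$o[1], voc, c(seen, head_node)) else list()
  c(list(term), rest)
}

#' Decode composite annotations from an RDF graph
#'
#' Every maximal annotation subgraph rooted at a model-entity URI (a subject
#' carrying the property predicate whose URI parses under the entity scheme)
#' is decoded into one [composite_annotation()]. Subgraphs violating the
#' annotation invariants are reported as per-entity warnings, not errors,
#' and skipped. Entities with no triples are retained as unannotated rows of
#' the corpus.
#'
#' @param models A list of `cellml_model` objects or a data.frame with
#'   columns `file`, `name`.
#' @param triples An [rdf_triples()] table.
#' @param vocabulary Predicate vocabulary.
#' @return An [annotated_corpus()].
#' @export
extract_annotations <- function(models, triples, vocabulary = default_vocabulary()) {
  voc <- vocabulary
  df <- as.data.frame(triples)
  if (is.data.frame(models)) {
    model_df <- models[, c("file", "name"), drop = FALSE]
    entities <- NULL
  } else {
    model_df <- data.frame(file = vapply(models, `[[`, "", "file"),
                           name = vapply(models, `[[`, "", "name"),
                           stringsAsFactors = FALSE)
    entities <- do.call(rbind, lapply(models, model_entities))
  }
  # model titles asserted in the graph override file-derived names
  if (nrow(df) > 0L) {
    titles <- df[df$p == voc[["model_title"]] & df$s_type == "iri", , drop = FALSE]
    for (i in seq_len(nrow(titles))) {
      hit <- match(titles$s[i], model_df$file)
      if (!is.na(hit)) model_df$name[hit] <- titles$o[i]
    }
  }
  subjects <- unique(df$s[df$p == voc[["property"]] & df$s_type == "iri"])
  subjects <- subjects[is_entity_uri(subjects)]
  subjects <- subjects[vapply(subjects, function(s) {
    sub("#.*$", "", s) %in% model_df$file
  }, TRUE)]
  annotations <- list()
  for (subj in sort(subjects)) {
    ann <- tryCatch(decode_one_annotation(df, subj, voc),
                    semdisc_error = function(e) {
                      semdisc_warning(paste0("invalid annotation subgraph at <", subj,
                                             ">: ", conditionMessage(e)),
                                      "semdisc_annotation_warning")
                      NULL
                    })
    if (!is.null(ann)) annotations[[length(annotations) + 1L]] <- ann
  }
  annotated_corpus(model_df, annotations, entities = entities)
}

decode_one_annotation <- function(df, subj, voc) {
  entity <- parse_entity_uri(subj)
  prop <- objects_of(df, subj, voc[["property"]])
  chem <- objects_of(df, subj, voc[["chemical"]])
  med <- objects_of(df, subj, voc[["mediator"]])
  spec <- objects_of(df, subj, voc[["species"]])
  gene <- objects_of(df, subj, voc[["gene"]])
  chain_at <- function(pred) {
    head <- objects_of(df, subj, pred)
    if (nrow(head) == 0L) return(list())
    decode_chain(df, head$o[1], voc)
  }
  composite_annotation(
    target = entity,
    property = decode_term(df, prop$o[1], voc),
    chemical = if (nrow(chem) > 0L) decode_term(df, chem$o[1], voc),
    source_location = chain_at(voc[["source"]]),
    sink_location = chain_at(voc[["sink"]]),
    located_in = chain_at(voc[["located_in"]]),
    mediator = if (nrow(med) > 0L) decode_term(df, med$o[1], voc),
    species = if (nrow(spec) > 0L) spec$o[1],
    gene = if (nrow(gene) > 0L) gene$o[1])
}
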