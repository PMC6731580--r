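# Free-text model discovery: decompose a query into dictionary-mapped
# ontology terms, match them against the annotation slots of every corpus
# entity in cascading stages (slot matches, then protein / species / gene
# enrichment), and rank by a weighted slot-match score. An entity matching
# both the property and the chemical of a query (e.g. a sodium flux for
# "flux of sodium") outranks chemical-only matches, which are still
# returned with a lower rank.

#' Default slot weights for ranking
#'
#' Property and chemical dominate (0.35 each), anatomical location 0.15,
#' protein mediator 0.10 and model-name match 0.05. The weights are
#' artifact-level configuration: only the induced order is scientifically
#' constrained (more matched slots never rank lower), the numbers are
#' exposed so deployments can retune.
#'
#' @return Named numeric vector over the five slots.
#' @export
default_weights <- function() {
  c(property = 0.35, chemical = 0.35, location = 0.15,
    mediator = 0.10, model_name = 0.05)
}

SLOTS <- c("property", "chemical", "location", "mediator", "model_name")

validate_weights <- function(weights) {
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !setequal(names(weights), SLOTS)) {
    abort_invalid_input(paste0("weights must be a named numeric vector over: ",
                               paste(SLOTS, collapse = ", ")))
  }
  if (any(weights <= 0)) abort_invalid_input("weights must be positive")
  weights[SLOTS] / sum(weights)
}

#' Which slots of an annotation do the mapped terms hit?
#' @keywords internal
matched_slots <- function(annotation, terms) {
  uris <- vapply(terms, term_uri, "")
  loc_uris <- vapply(annotation_location_terms(annotation), term_uri, "")
  out <- list()
  add <- function(term, slot) out[[length(out) + 1L]] <<- list(term = term, slot = slot)
  for (t in terms) {
    u <- term_uri(t)
    if (u == term_uri(annotation$property)) add(t, "property")
    if (!is.null(annotation$chemical) && u == term_uri(annotation$chemical)) add(t, "chemical")
    if (u %in% loc_uris) add(t, "location")
    if (!is.null(annotation$mediator) && u == term_uri(annotation$mediator)) add(t, "mediator")
  }
  out
}

#' Score one entity against the mapped query terms
#'
#' The score is the sum of the (normalized) weights of the slots hit by at
#' least one mapped term; it is 0 when nothing matches and at most 1 when
#' every slot matches.
#'
#' @param annotation The entity's [composite_annotation()].
#' @param mapped_terms List of [ontology_term()]s from [map_tokens()].
#' @param weights Slot weights (normalized internally).
#' @param model_name_matched Whether a query token matched the model name.
#' @return A score in `[0, 1]`.
#' @export
score_entity <- function(annotation, mapped_terms, weights = default_weights(),
                         model_name_matched = FALSE) {
  weights <- validate_weights(weights)
  hits <- matched_slots(annotation, mapped_terms)
  slots <- unique(vapply(hits, `[[`, "", "slot"))
  if (model_name_matched) slots <- unique(c(slots, "model_name"))
  sum(weights[slots])
}

mediator_accession <- function(annotation) {
  if (is.null(annotation$mediator)) return(NULL)
  if (!annotation$mediator$prefix %in% c("PR", "UNIPROT")) return(NULL)
  basename_uri(term_uri(annotation$mediator))
}

#' Search an annotated corpus with free text
#'
#' The cascade: (1) tokenize the query and map tokens to ontology terms via
#' the dictionary; (2) match the mapped terms against annotation slots
#' (property, chemical, location, mediator) through the corpus term index
#' and match raw tokens against model names; (3) enrich surviving entities
#' with their protein accession, species and gene (enrichment never filters
#' — entities without protein annotations still appear); (4) score, sort
#' descending, break ties deterministically (variable-level entities before
#' component-level, then model name, then entity URI).
#'
#' @param corpus An [annotated_corpus()].
#' @param dict A `term_dictionary` from [read_dictionary()].
#' @param query_text Free-text query, e.g. `"flux of sodium"`.
#' @param weights Slot weights; see [default_weights()].
#' @param labels A [label_cache()] for description rendering; defaults to
#'   the labels carried by the corpus terms.
#' @return An object of class `ranked_results`; its `results` element is a
#'   list of search results, and `as.data.frame()` tabulates them. When no
#'   token maps, the result set is empty and the unmapped tokens are
#'   reported in the `unmapped` element.
#' @export
search_corpus <- function(corpus, dict, query_text, weights = default_weights(),
                          labels = corpus_labels(corpus)) {
  weights <- validate_weights(weights)
  tokens <- tokenize(query_text)
  mapping <- map_tokens(dict, tokens)
  mapped_terms <- lapply(mapping$hits, `[[`, "term")
  # stage 1a: slot matches via the term index
  idx <- corpus$index$by_term
  slot_entities <- unique(idx$entity[idx$term %in% vapply(mapped_terms, term_uri, "")])
  # stage 1b: model-name matches (case-insensitive substring on raw tokens)
  name_models <- character()
  for (tok in tokens) {
    hit <- grepl(tok, tolower(corpus$models$name), fixed = TRUE)
    name_models <- c(name_models, corpus$models$file[hit])
  }
  name_models <- unique(name_models)
  name_entities <- names(corpus$index$by_entity)[
    vapply(corpus$index$by_entity, function(a) a$target$model_file, "") %in% name_models]
  candidates <- union(slot_entities, name_entities)
  results <- list()
  for (uri in candidates) {
    a <- corpus_annotation_for(corpus, uri)
    if (is.null(a)) next
    name_matched <- a$target$model_file %in% name_models
    score <- score_entity(a, mapped_terms, weights, model_name_matched = name_matched)
    if (score <= 0) next
    hits <- matched_slots(a, mapped_terms)
    if (name_matched) {
      hits[[length(hits) + 1L]] <- list(term = NULL, slot = "model_name")
    }
    # stage 2: enrichment
    model_name <- corpus$models$name[match(a$target$model_file, corpus$models$file)]
    results[[length(results) + 1L]] <- structure(
      list(entity = a$target, uri = uri, score = score, matched_terms = hits,
           description = render_description(a, labels),
           protein = mediator_accession(a),
           species = a$species, gene = a$gene, model_name = model_name),
      class = "search_result")
  }
  results <- order_results(results)
  structure(list(query = query_text, results = results,
                 unmapped = mapping$unmapped),
            class = "ranked_results")
}

order_results <- function(results) {
  if (length(results) == 0L) return(results)
  score <- vapply(results, `[[`, 0, "score")
  is_component <- vapply(results, function(r) is.null(r$entity$variable), TRUE)
  model <- vapply(results, `[[`, "", "model_name")
  uri <- vapply(results, `[[`, "", "uri")
  results[order(-score, is_component, model, uri)]
}

#' @export
print.ranked_results <- function(x, ...) {
  cat("query: \"", x$query, "\" — ", length(x$results), " result(s)\n", sep = "")
  if (length(x$unmapped) > 0L) {
    cat("unmapped token(s):", paste(x$unmapped, collapse = ", "), "\n")
  }
  df <- as.data.frame(x)
  if (nrow(df) > 0L) print(df[, c("entity", "score", "description")], right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ranked_results <- function(x, ...) {
  if (length(x$results) == 0L) {
    return(data.frame(entity = character(), model = character(),
                      component = character(), variable = character(),
                      score = numeric(), slots = character(),
                      description = character(), protein = character(),
                      species = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(
      entity = r$uri,
      model = r$model_name,
      component = r$entity$component,
      variable = r$entity$variable %||% NA_character_,
      score = r$score,
      slots = paste(sort(unique(vapply(r$matched_terms, `[[`, "", "slot"))),
                    collapse = ","),
      description = r$description,
      protein = r$protein %||% NA_character_,
      species = r$species %||% NA_character_,
      gene = r$gene %||% NA_character_,
      stringsAsFactors = FALSE)
  }))
}
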