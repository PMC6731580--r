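# Recommender: given a selected model entity, assemble its overview card
# and rank candidate models from other files that share anatomical location,
# ordering protein-mediated candidates by percent identity to the selected
# entity's mediator. Semantic (shared-location) and sequence evidence are
# combined by listing sequence-ranked candidates first; the rank_score
# constants are configuration, since only "more relevant closer to the top"
# is scientifically constrained.

#' Overview card for a selected entity
#'
#' Assembled purely from the corpus annotations and the label cache: the
#' anatomical location(s), the rendered biological meaning, species, gene
#' and protein name, the mediator name/URI tooltip info, and a link to the
#' model file. Fields are absent exactly when the annotation lacks them.
#'
#' @param corpus An [annotated_corpus()].
#' @param entity_uri Canonical entity URI.
#' @param labels A [label_cache()].
#' @return A list of class `overview_card`.
#' @export
overview <- function(corpus, entity_uri, labels = corpus_labels(corpus)) {
  a <- corpus_annotation_for(corpus, entity_uri)
  if (is.null(a)) {
    if (!entity_uri %in% corpus$entities$uri) {
      abort_not_found(paste0("unknown entity: <", entity_uri, ">"))
    }
    abort_not_found(paste0("entity <", entity_uri, "> carries no annotation"))
  }
  locs <- vapply(annotation_location_terms(a), function(t) resolve_label(t, labels), "")
  structure(
    list(entity = a$target,
         anatomical_location = unique(locs),
         biological_meaning = render_description(a, labels),
         species = a$species, gene = a$gene,
         protein_name = if (!is.null(a$mediator)) resolve_label(a$mediator, labels),
         protein_accession = mediator_accession(a),
         mediator_info = if (!is.null(a$mediator)) {
           list(name = resolve_label(a$mediator, labels), uri = term_uri(a$mediator))
         },
         model_link = a$target$model_file),
    class = "overview_card")
}

#' @export
print.overview_card <- function(x, ...) {
  cat("entity:   <", construct_entity_uri(x$entity), ">\n", sep = "")
  cat("meaning:  ", x$biological_meaning, "\n", sep = "")
  cat("location: ", paste(x$anatomical_location, collapse = "; "), "\n", sep = "")
  if (!is.null(x$species)) cat("species:  ", x$species, "\n", sep = "")
  if (!is.null(x$gene)) cat("gene:     ", x$gene, "\n", sep = "")
  if (!is.null(x$protein_name)) cat("protein:  ", x$protein_name,
                                    if (!is.null(x$protein_accession))
                                      paste0(" (", x$protein_accession, ")"),
                                    "\n", sep = "")
  invisible(x)
}

location_uris <- function(a) unique(vapply(annotation_location_terms(a), term_uri, ""))

#' Recommend similar and alternative models
#'
#' Candidates are annotated entities of other model files whose location
#' chains (source, sink or located-in) intersect the selected entity's —
#' sharing a membrane or compartment. One candidate is kept per model: the
#' entity sharing the most location terms. Candidates whose mediator has a
#' retrievable protein sequence are ranked first, by percent identity to the
#' selected entity's protein (via [similarity_matrix()]); candidates
#' without sequences follow, ordered by shared-location count then URI. A
#' failed sequence fetch degrades that candidate to location-only with a
#' warning rather than failing the recommendation.
#'
#' Two alternative groups are also reported: entities carrying the same
#' protein (by mediator name) in a different species, and other models from
#' the selected model's workspace directory.
#'
#' @param corpus An [annotated_corpus()].
#' @param entity_uri Canonical URI of the selected entity.
#' @param seq_source Optional [sequence_source()] providing mediator protein
#'   sequences.
#' @param location_weight Rank-score constant for location-only candidates:
#'   `rank_score = location_weight * shared / selected-location-count`.
#' @param labels A [label_cache()].
#' @return A list of class `recommendations` with elements `selected`,
#'   `overview`, `similar` (ordered list of recommendation records) and
#'   `alternatives`.
#' @export
recommend <- function(corpus, entity_uri, seq_source = NULL,
                      location_weight = 0.5, labels = corpus_labels(corpus)) {
  sel <- corpus_annotation_for(corpus, entity_uri)
  if (is.null(sel)) abort_not_found(paste0("unknown or unannotated entity: <", entity_uri, ">"))
  sel_locs <- location_uris(sel)
  sel_acc <- mediator_accession(sel)
  sel_species <- sel$species
  sel_name <- if (!is.null(sel$mediator)) term_label(sel$mediator)

  # candidate entities from other models sharing at least one location term
  cand <- list()
  for (uri in names(corpus$index$by_entity)) {
    a <- corpus$index$by_entity[[uri]]
    if (a$target$model_file == sel$target$model_file) next
    shared <- intersect(sel_locs, location_uris(a))
    if (length(shared) == 0L) next
    cand[[length(cand) + 1L]] <- list(uri = uri, annotation = a, shared = length(shared))
  }
  # one candidate per model: most shared location terms, then URI
  if (length(cand) > 0L) {
    files <- vapply(cand, function(x) x$annotation$target$model_file, "")
    keep <- integer()
    for (f in sort(unique(files))) {
      members <- which(files == f)
      members <- members[order(-vapply(cand[members], `[[`, 0, "shared"),
                               vapply(cand[members], `[[`, "", "uri"))]
      keep <- c(keep, members[1])
    }
    cand <- cand[keep]
  }

  recs <- lapply(cand, function(x) {
    acc <- mediator_accession(x$annotation)
    sim <- NULL
    basis <- "same_location"
    if (!is.null(acc) && !is.null(sel_acc) && !is.null(seq_source)) {
      sim <- tryCatch({
        recs_sel <- fetch_sequence(sel_acc, seq_source)
        recs_cand <- fetch_sequence(acc, seq_source)
        m <- similarity_matrix(list(recs_sel, recs_cand))
        m[sel_acc, acc]
      }, semdisc_error = function(e) {
        semdisc_warning(paste0("sequence unavailable for ", acc,
                               "; candidate degraded to location-only: ",
                               conditionMessage(e)),
                        "semdisc_sequence_warning")
        NULL
      })
      if (!is.null(sim)) basis <- c("same_location", "sequence_similarity")
    }
    rank_score <- if (!is.null(sim)) sim / 100 else location_weight * x$shared / length(sel_locs)
    list(candidate = x$annotation$target, uri = x$uri, basis = basis,
         similarity = sim, shared_locations = x$shared, rank_score = rank_score)
  })
  has_sim <- vapply(recs, function(r) !is.null(r$similarity), TRUE)
  sim_block <- recs[has_sim]
  loc_block <- recs[!has_sim]
  if (length(sim_block) > 0L) {
    sim_block <- sim_block[order(-vapply(sim_block, `[[`, 0, "similarity"),
                                 vapply(sim_block, `[[`, "", "uri"))]
  }
  if (length(loc_block) > 0L) {
    loc_block <- loc_block[order(-vapply(loc_block, `[[`, 0, "shared_locations"),
                                 vapply(loc_block, `[[`, "", "uri"))]
  }
  similar <- c(sim_block, loc_block)

  # alternative group: same protein (by mediator name), different species
  same_protein <- list()
  if (!is.null(sel_name)) {
    for (uri in names(corpus$index$by_entity)) {
      if (uri == entity_uri) next
      a <- corpus$index$by_entity[[uri]]
      nm <- if (!is.null(a$mediator)) term_label(a$mediator)
      if (is.null(nm) || !identical(nm, sel_name)) next
      if (!is.null(sel_species) && !is.null(a$species) &&
          tolower(a$species) != tolower(sel_species)) {
        same_protein[[length(same_protein) + 1L]] <-
          list(entity = a$target, uri = uri, species = a$species)
      }
    }
    same_protein <- same_protein[order(vapply(same_protein, `[[`, "", "uri"))]
  }
  # alternative group: other models in the selected model's workspace directory
  sel_dir <- dirname(sel$target$model_file)
  ws_models <- corpus$models$file[dirname(corpus$models$file) == sel_dir &
                                    corpus$models$file != sel$target$model_file]
  structure(
    list(selected = entity_uri,
         overview = overview(corpus, entity_uri, labels),
         similar = similar,
         alternatives = list(same_protein_other_species = same_protein,
                             same_workspace_organ = sort(ws_models))),
    class = "recommendations")
}

#' @export
print.recommendations <- function(x, ...) {
  cat("selected: <", x$selected, ">\n", sep = "")
  cat(length(x$similar), "similar model(s):\n")
  for (r in x$similar) {
    cat("  <", r$uri, ">",
        if (!is.null(r$similarity)) paste0("  identity ", formatC(r$similarity, format = "f", digits = 2), "%"),
        "  [", paste(r$basis, collapse = "+"), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.recommendations <- function(x, ...) {
  if (length(x$similar) == 0L) {
    return(data.frame(candidate = character(), similarity = numeric(),
                      shared_locations = integer(), rank_score = numeric(),
                      basis = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$similar, function(r) {
    data.frame(candidate = r$uri,
               similarity = r$similarity %||% NA_real_,
               shared_locations = r$shared_locations,
               rank_score = r$rank_score,
               basis = paste(r$basis, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
}
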