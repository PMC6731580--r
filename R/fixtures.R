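# Deterministic synthetic-corpus generator. Emulates a cohort of annotated
# epithelial-transport models: per model a CellML file with membrane and
# cytosol components, a sibling Turtle annotation document with composite
# annotations (fluxes with source/sink chains and protein mediators,
# concentrations with located-in chains), a FASTA of mediator proteins
# mutated from a reference at rates implied by the planted identities, and
# a dictionary covering every label used. Same seed, byte-identical output.

#' Fixture ontology terms (reserved example namespace)
#'
#' All fixture terms live under `https://example.org/` so that synthetic
#' data can never be mistaken for real OPB/FMA/ChEBI/PR identifiers.
#'
#' @return Named list of [ontology_term()]s.
#' @export
fixture_terms <- function() {
  ex <- function(id, label) ontology_term(paste0("https://example.org/onto/", id), label)
  list(
    flux = ex("OPB_00593", "flux"),
    concentration = ex("OPB_00340", "concentration"),
    sodium = ex("CHEBI_29101", "sodium"),
    hydrogen = ex("CHEBI_15378", "hydrogen"),
    glucose = ex("CHEBI_17234", "glucose"),
    potassium = ex("CHEBI_29103", "potassium"),
    apical_membrane = ex("FMA_67697", "apical plasma membrane"),
    basolateral_membrane = ex("FMA_84669", "basolateral plasma membrane"),
    cytosol = ex("FMA_66836", "cytosol"),
    tubule_lumen = ex("FMA_74268", "tubule lumen"),
    interstitial_fluid = ex("FMA_9673", "interstitial fluid"),
    proximal_tubule = ex("FMA_17693", "proximal tubule"),
    epithelial_cell = ex("FMA_66768", "epithelial cell"),
    epithelial_cell_cytosol = ex("FMA_70022", "epithelial cell cytosol"),
    nhe3 = ex("PR_000014558", "sodium/hydrogen exchanger 3"))
}

#' The running worked example: an annotated sodium flux
#'
#' A composite annotation describing sodium flux from the proximal tubule to
#' the epithelial cell cytosol via sodium/hydrogen exchanger 3, bound to the
#' variable `J_NHE3_Na` of component `NHE3` in `weinstein_1995.cellml`.
#' Useful for demonstrations and as a decoding reference.
#'
#' @return A [composite_annotation()].
#' @examples
#' render_description(example_nhe3_annotation())
#' @export
example_nhe3_annotation <- function() {
  tm <- fixture_terms()
  composite_annotation(
    target = model_entity("weinstein_1995.cellml", "NHE3", "J_NHE3_Na"),
    property = tm$flux,
    chemical = tm$sodium,
    source_location = list(tm$proximal_tubule),
    sink_location = list(tm$epithelial_cell_cytosol),
    mediator = tm$nhe3,
    species = "Homo sapiens", gene = "SLC9A3")
}

#' Specification of a synthetic corpus
#'
#' @param n_models Number of models (>= 1).
#' @param membranes Which membranes models carry: subset of
#'   `c("apical", "basolateral")`.
#' @param transporters_per_model Flux variables per model.
#' @param chemicals Labels of the non-sodium chemicals cycled through the
#'   apical fluxes (must be names of [fixture_terms()]).
#' @param planted_identities Percent identities of candidate mediator
#'   proteins relative to the reference protein of model 1; models
#'   `2 .. 1+length(planted_identities)` carry these candidates on their
#'   basolateral sodium flux.
#' @param seed Integer RNG seed; the whole output tree is a pure function of
#'   the spec including this seed.
#' @param protein_length Length of the reference protein.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_models = 4, membranes = c("apical", "basolateral"),
                        transporters_per_model = 2,
                        chemicals = c("glucose", "hydrogen", "potassium"),
                        planted_identities = c(90, 50, 20),
                        seed = 42, protein_length = 240) {
  if (n_models < 1) abort_invalid_input("n_models must be >= 1")
  if (any(planted_identities < 0 | planted_identities > 100)) {
    abort_invalid_input("planted identities must be percentages in [0, 100]")
  }
  if (!all(membranes %in% c("apical", "basolateral"))) {
    abort_invalid_input("membranes must be a subset of apical/basolateral")
  }
  structure(list(n_models = n_models, membranes = membranes,
                 transporters_per_model = transporters_per_model,
                 chemicals = chemicals,
                 planted_identities = planted_identities,
                 seed = as.integer(seed), protein_length = protein_length),
            class = "corpus_spec")
}

# run fn under a derived seed without disturbing the caller's RNG state
with_derived_seed <- function(seed, salt, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  # keep derived seeds positive and below 2^31
  set.seed((as.double(seed) * 7919 + salt) %% 2147483647)
  fn()
}

random_protein <- function(length) {
  paste(sample(AA_ALPHABET[AA_ALPHABET != "X"], length, replace = TRUE), collapse = "")
}

# substitute exactly round(n * (1 - identity/100)) positions, each to a
# different residue, so the realized per-site identity equals the plant
mutate_protein <- function(reference, identity) {
  res <- strsplit(reference, "")[[1]]
  k <- round(length(res) * (1 - identity / 100))
  aas <- AA_ALPHABET[AA_ALPHABET != "X"]
  for (i in sample(length(res), k)) {
    res[i] <- sample(setdiff(aas, res[i]), 1L)
  }
  paste(res, collapse = "")
}

fixture_species <- c("Homo sapiens", "Rattus norvegicus", "Mus musculus",
                     "Oryctolagus cuniculus", "Canis lupus familiaris")

cellml_model_text <- function(model_name, components) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<model name=\"", model_name, "\"",
                    " xmlns=\"", CELLML_1_0_NS, "\"",
                    " xmlns:cmeta=\"", CMETA_NS, "\">"))
  for (comp in names(components)) {
    lines <- c(lines, paste0("  <component name=\"", comp,
                             "\" cmeta:id=\"", comp, "\">"))
    for (v in components[[comp]]) {
      lines <- c(lines,
                 paste0("    <variable name=\"", v$name, "\" units=\"", v$units,
                        "\" cmeta:id=\"", comp, ".", v$name, "\"/>"))
    }
    lines <- c(lines, "  </component>")
  }
  c(lines, "</model>")
}

#' Generate a synthetic annotated corpus on disk
#'
#' Writes, per model, one CellML file and one sibling Turtle annotation
#' document; plus `proteins.fasta` (mediator sequences), `dictionary.tsv`
#' (covering all labels used), `prefixes.tsv` and `manifest.tsv` listing
#' every annotated entity with its expected annotation summary. Model 1's
#' basolateral sodium flux is mediated by the reference protein; the next
#' `length(planted_identities)` models carry candidate proteins mutated to
#' the planted identities.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame, invisibly; written as
#'   `manifest.tsv`.
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    abort_invalid_input(paste0("output directory not writable: ", out_dir))
  }
  tm <- fixture_terms()

  # --- proteins ------------------------------------------------------------
  reference <- with_derived_seed(spec$seed, 1, function() random_protein(spec$protein_length))
  accs <- c("FIXP000", sprintf("FIXP%03d", seq_along(spec$planted_identities)))
  seqs <- c(reference,
            vapply(seq_along(spec$planted_identities), function(i) {
              with_derived_seed(spec$seed, 100 + i, function() {
                mutate_protein(reference, spec$planted_identities[i])
              })
            }, ""))
  names(seqs) <- accs
  n_mediated <- min(spec$n_models, 1L + length(spec$planted_identities))

  protein_term <- function(acc, i) {
    # models 1 and 2 share the protein name (orthologs); later ones differ
    nm <- if (i <= 2L) "sodium/hydrogen exchanger-like protein"
          else paste0("sodium transport protein ", i)
    ontology_term(paste0("https://example.org/protein/", acc), nm)
  }

  manifest <- list()
  dict_terms <- list()
  note_dict <- function(key, term) {
    dict_terms[[paste0(key, "\x01", term_uri(term))]] <<- list(key = key, term = term)
  }
  for (key in c("flux", "concentration", "sodium", "hydrogen", "glucose", "potassium")) {
    note_dict(key, tm[[key]])
  }
  note_dict("apical", tm$apical_membrane)
  note_dict("basolateral", tm$basolateral_membrane)
  note_dict("membrane", tm$apical_membrane)
  note_dict("membrane", tm$basolateral_membrane)
  note_dict("cytosol", tm$cytosol)
  note_dict("lumen", tm$tubule_lumen)
  note_dict("interstitial", tm$interstitial_fluid)
  note_dict("proximal tubule", tm$proximal_tubule)

  for (i in seq_len(spec$n_models)) {
    file <- sprintf("model%02d.cellml", i)
    model_name <- sprintf("epithelial transport model %02d", i)
    species <- fixture_species[(i - 1L) %% length(fixture_species) + 1L]
    chem_label <- spec$chemicals[(i - 1L) %% length(spec$chemicals) + 1L]
    chem <- tm[[chem_label]]
    if (is.null(chem)) abort_invalid_input(paste0("unknown fixture chemical: ", chem_label))

    components <- list()
    annotations <- list()
    add_ann <- function(a, kind, membrane, acc, planted) {
      annotations[[length(annotations) + 1L]] <<- a
      manifest[[length(manifest) + 1L]] <<- data.frame(
        entity = construct_entity_uri(a$target), model_file = file,
        kind = kind, chemical = term_label(a$chemical) %||% NA_character_,
        membrane = membrane %||% NA_character_,
        mediator_accession = acc %||% NA_character_,
        planted_identity = planted %||% NA_real_,
        stringsAsFactors = FALSE)
    }

    if ("basolateral" %in% spec$membranes) {
      comp <- "basolateral_membrane"
      components[[comp]] <- list(list(name = "J_Na", units = "flux_units"))
      acc <- if (i <= n_mediated) accs[i] else NULL
      mediator <- if (!is.null(acc)) protein_term(acc, i)
      add_ann(composite_annotation(
        target = model_entity(file, comp, "J_Na"),
        property = tm$flux, chemical = tm$sodium,
        source_location = list(tm$cytosol, tm$basolateral_membrane),
        sink_location = list(tm$interstitial_fluid),
        mediator = mediator, species = species,
        gene = if (!is.null(mediator)) "slc9-like"),
        kind = "flux", membrane = "basolateral", acc = acc,
        planted = if (!is.null(acc) && i > 1L) spec$planted_identities[i - 1L])
    }
    if ("apical" %in% spec$membranes) {
      comp <- "apical_membrane"
      vars <- list()
      n_apical <- max(1L, spec$transporters_per_model - as.integer("basolateral" %in% spec$membranes))
      apical_chems <- unique(c(chem_label,
                               spec$chemicals))[seq_len(min(n_apical, length(spec$chemicals)))]
      for (cl in apical_chems) {
        ct <- tm[[cl]]
        vars[[length(vars) + 1L]] <- list(name = paste0("J_", cl), units = "flux_units")
        add_ann(composite_annotation(
          target = model_entity(file, comp, paste0("J_", cl)),
          property = tm$flux, chemical = ct,
          source_location = list(tm$tubule_lumen, tm$apical_membrane),
          sink_location = list(tm$cytosol),
          species = species),
          kind = "flux", membrane = "apical", acc = NULL, planted = NULL)
      }
      components[[comp]] <- vars
    }
    components[["cytosol"]] <- list(list(name = "C_Na", units = "mM"),
                                    list(name = paste0("C_", chem_label), units = "mM"))
    add_ann(composite_annotation(
      target = model_entity(file, "cytosol", "C_Na"),
      property = tm$concentration, chemical = tm$sodium,
      located_in = list(tm$cytosol, tm$epithelial_cell),
      species = species),
      kind = "concentration", membrane = NULL, acc = NULL, planted = NULL)
    add_ann(composite_annotation(
      target = model_entity(file, "cytosol", paste0("C_", chem_label)),
      property = tm$concentration, chemical = chem,
      located_in = list(tm$cytosol, tm$epithelial_cell),
      species = species),
      kind = "concentration", membrane = NULL, acc = NULL, planted = NULL)

    writeLines(cellml_model_text(model_name, components),
               file.path(out_dir, file), useBytes = TRUE)
    corpus_part <- annotated_corpus(
      data.frame(file = file, name = model_name, stringsAsFactors = FALSE),
      annotations)
    write_annotation_graph(encode_annotations(corpus_part),
                           file.path(out_dir, sub("\\.cellml$", ".ttl", file)),
                           dialect = "turtle")
  }

  write_fasta(seqs[seq_len(n_mediated)], file.path(out_dir, "proteins.fasta"))

  dict <- structure(list(), class = "term_dictionary")
  for (entry in dict_terms) {
    dict[[entry$key]] <- c(dict[[entry$key]], list(entry$term))
  }
  write_dictionary(dict, file.path(out_dir, "dictionary.tsv"))
  reg <- default_prefix_registry()
  writeLines(paste(reg$prefix, reg$stem, sep = "\t"),
             file.path(out_dir, "prefixes.tsv"), useBytes = TRUE)

  manifest <- do.call(rbind, manifest)
  manifest <- manifest[order(manifest$entity), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a generated corpus manifest
#' @param dir Corpus directory.
#' @return The manifest data.frame.
#' @export
read_manifest <- function(dir) {
  utils::read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
}
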