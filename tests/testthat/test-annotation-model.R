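test_that("entity URIs construct and parse as file#component.variable", {
  e <- model_entity("weinstein_1995.cellml", "NHE3", "J_NHE3_Na")
  expect_identical(construct_entity_uri(e), "weinstein_1995.cellml#NHE3.J_NHE3_Na")
  p <- parse_entity_uri("weinstein_1995.cellml#NHE3.J_NHE3_Na")
  expect_identical(p$model_file, "weinstein_1995.cellml")
  expect_identical(p$component, "NHE3")
  expect_identical(p$variable, "J_NHE3_Na")

  # component-level entity: no variable part
  expect_identical(construct_entity_uri(model_entity("m.cellml", "C")), "m.cellml#C")
  pc <- parse_entity_uri("m.cellml#C")
  expect_null(pc$variable)

  # the FIRST dot separates component from variable; later dots belong to it
  pv <- parse_entity_uri("m.cellml#comp.var.with.dots")
  expect_identical(pv$component, "comp")
  expect_identical(pv$variable, "var.with.dots")
})

test_that("malformed entity URIs and invalid entities are rejected", {
  expect_error(parse_entity_uri("m.cellml"), class = "semdisc_malformed_uri")
  expect_error(parse_entity_uri("m.cellml#"), class = "semdisc_malformed_uri")
  expect_error(parse_entity_uri("a#b#c"), class = "semdisc_malformed_uri")
  expect_error(model_entity("m.cellml", ""), class = "semdisc_invalid_entity")
  expect_error(model_entity("", "C"), class = "semdisc_invalid_entity")
})

test_that("parse after construct is the identity on generated entities", {
  set.seed(101)
  for (i in seq_len(1000)) {
    e <- random_entity()
    rt <- parse_entity_uri(construct_entity_uri(e))
    expect_identical(rt$model_file, e$model_file)
    expect_identical(rt$component, e$component)
    expect_identical(rt$variable, e$variable)
  }
})

test_that("ontology terms derive prefixes from the registry and compare by URI", {
  t1 <- ontology_term("https://example.org/onto/CHEBI_29101", "sodium")
  expect_identical(t1$prefix, "CHEBI")
  expect_identical(ontology_term("http://purl.org/sig/ont/fma/fma66836")$prefix, "FMA")
  expect_identical(ontology_term("http://unknown.example.net/term/1")$prefix, "OTHER")
  # equality ignores label, trims whitespace, respects case
  t2 <- ontology_term("  https://example.org/onto/CHEBI_29101 ")
  expect_true(t1 == t2)
  expect_false(t1 == ontology_term("https://example.org/onto/CHEBI_29101X"))
  expect_error(ontology_term("not a uri"), class = "semdisc_malformed_uri")
})

test_that("the sodium-flux example renders its canonical description", {
  a <- example_nhe3_annotation()
  expect_identical(
    render_description(a),
    "sodium flux from proximal tubule to epithelial cell cytosol via sodium/hydrogen exchanger 3")
})

test_that("description templates collapse absent slots grammatically", {
  tm <- fixture_terms()
  conc <- composite_annotation(
    target = model_entity("m.cellml", "cytosol", "C_Na"),
    property = tm$concentration, chemical = tm$sodium,
    located_in = list(tm$cytosol))
  expect_identical(render_description(conc), "sodium concentration in cytosol")

  # no chemical, no mediator, no dangling connectives
  bare <- composite_annotation(
    target = model_entity("m.cellml", "c", "v"),
    property = tm$flux, sink_location = list(tm$cytosol))
  expect_identical(render_description(bare), "flux to cytosol")
  expect_false(grepl("via|from", render_description(bare)))
})

test_that("rendering matches an independent template oracle on 50 fixtures", {
  set.seed(202)
  for (i in seq_len(50)) {
    a <- random_annotation()
    expect_identical(render_description(a), oracle_render(a))
    # deterministic: same annotation, same string
    expect_identical(render_description(a), render_description(a))
  }
})

test_that("a term without a label raises an unresolved-label error naming it", {
  a <- composite_annotation(
    target = model_entity("m.cellml", "c", "v"),
    property = ontology_term("https://example.org/onto/OPB_99999"))
  err <- expect_error(render_description(a), class = "semdisc_unresolved_label")
  expect_match(conditionMessage(err), "OPB_99999")
  # but resolvable through a label cache
  cache <- label_cache()
  label_put(cache, "https://example.org/onto/OPB_99999", "mystery property")
  expect_identical(render_description(a, cache), "mystery property")
})

test_that("annotation invariants are enforced", {
  tm <- fixture_terms()
  e <- model_entity("m.cellml", "c", "v")
  expect_error(composite_annotation(e, property = "flux"),
               class = "semdisc_invalid_input")
  # process and state location styles are mutually exclusive
  expect_error(composite_annotation(e, tm$flux,
                                    source_location = list(tm$cytosol),
                                    located_in = list(tm$cytosol)),
               class = "semdisc_invalid_input")
  # no duplicate terms within a chain
  expect_error(composite_annotation(e, tm$flux,
                                    source_location = list(tm$cytosol, tm$cytosol)),
               class = "semdisc_invalid_input")
})

test_that("corpus indexes rebuild from the annotation set to identical content", {
  set.seed(303)
  annotations <- lapply(seq_len(20), function(i) random_annotation())
  corpus <- corpus_of(annotations)
  rebuilt <- build_corpus_index(corpus$annotations)
  expect_identical(rebuilt$by_term, corpus$index$by_term)
  expect_identical(sort(names(rebuilt$by_entity)), sort(names(corpus$index$by_entity)))
  # every annotation target is a corpus entity
  expect_true(all(names(corpus$index$by_entity) %in% corpus$entities$uri))
  # an annotation whose model is absent from the corpus is rejected
  expect_error(
    annotated_corpus(data.frame(file = "other.cellml", name = "x"), annotations[1]),
    class = "semdisc_invalid_input")
})
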