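test_that("slot scores add the stated weights", {
  tm <- fixture_terms()
  a <- composite_annotation(
    target = model_entity("m.cellml", "bm", "J_Na"),
    property = tm$flux, chemical = tm$sodium,
    source_location = list(tm$cytosol), sink_location = list(tm$interstitial_fluid))
  # property + chemical under the default weights
  expect_equal(score_entity(a, list(tm$flux, tm$sodium)), 0.70)
  expect_equal(score_entity(a, list(tm$glucose)), 0)
  expect_equal(score_entity(a, list(tm$sodium)), 0.35)
  expect_equal(score_entity(a, list(tm$flux, tm$sodium, tm$cytosol)), 0.85)
  expect_equal(score_entity(a, list(), model_name_matched = TRUE), 0.05)
})

test_that("scores equal an independent recomputation over random match subsets", {
  set.seed(77)
  w <- default_weights()
  tm <- fixture_terms()
  for (i in 1:40) {
    a <- random_annotation()
    terms <- sample(tm, sample.int(5, 1))
    got <- score_entity(a, terms)
    # independent recomputation: indicator per slot times weight
    uris <- vapply(terms, function(t) t$uri, "")
    prop <- a$property$uri %in% uris
    chem <- !is.null(a$chemical) && a$chemical$uri %in% uris
    locs <- vapply(c(a$source_location, a$sink_location, a$located_in),
                   function(t) t$uri, "")
    loc <- length(intersect(locs, uris)) > 0
    med <- !is.null(a$mediator) && a$mediator$uri %in% uris
    want <- sum(w[c("property", "chemical", "location", "mediator")] *
                  c(prop, chem, loc, med))
    expect_equal(got, unname(want))
  }
})

test_that("invalid weight vectors are rejected", {
  tm <- fixture_terms()
  a <- random_annotation()
  expect_error(score_entity(a, list(tm$flux), weights = c(property = 1)),
               class = "semdisc_invalid_input")
  w <- default_weights(); w["location"] <- -0.1
  expect_error(score_entity(a, list(tm$flux), weights = w),
               class = "semdisc_invalid_input")
})

test_that("searching the generated cohort ranks sodium fluxes first", {
  corpus <- mini_corpus()
  dict <- mini_dictionary()
  res <- search_corpus(corpus, dict, "flux of sodium")
  df <- as.data.frame(res)
  manifest <- read_manifest(mini_corpus_dir())
  flux_na <- manifest$entity[manifest$kind == "flux" & manifest$chemical == "sodium"]
  conc_only <- manifest$entity[manifest$kind == "concentration"]
  # every planted sodium flux is returned and outranks every concentration entity
  expect_true(all(flux_na %in% df$entity))
  flux_pos <- match(flux_na, df$entity)
  conc_pos <- match(intersect(conc_only, df$entity), df$entity)
  expect_true(max(flux_pos) < min(conc_pos))
  # descriptions come from the annotation renderer
  expect_match(df$description[df$entity == flux_na[1]], "^sodium flux from")
  # scores are non-increasing down the list
  expect_true(all(diff(df$score) <= 0))
})

test_that("unmappable queries return empty results with diagnostics", {
  res <- search_corpus(mini_corpus(), mini_dictionary(), "xyzzy")
  expect_length(res$results, 0L)
  expect_identical(res$unmapped, "xyzzy")
})

test_that("model-name matches surface a model's annotated entities", {
  corpus <- mini_corpus()
  res <- search_corpus(corpus, mini_dictionary(), "epithelial")
  df <- as.data.frame(res)
  expect_gt(nrow(df), 0L)
  expect_true(all(df$slots == "model_name"))
  expect_true(all(df$score == unname(default_weights()["model_name"])))
})

test_that("ranking matches a brute-force per-entity scorer on the cohort", {
  corpus <- mini_corpus()
  dict <- mini_dictionary()
  for (q in c("flux of sodium", "sodium concentration in cytosol",
              "glucose flux", "basolateral sodium")) {
    res <- search_corpus(corpus, dict, q)
    df <- as.data.frame(res)
    # oracle: score every annotated entity independently, sort the same way
    terms <- lapply(map_tokens(dict, tokenize(q))$hits, `[[`, "term")
    oracle <- do.call(rbind, lapply(names(corpus$index$by_entity), function(uri) {
      a <- corpus$index$by_entity[[uri]]
      data.frame(entity = uri, score = score_entity(a, terms),
                 is_comp = is.null(a$target$variable),
                 model = corpus$models$name[match(a$target$model_file, corpus$models$file)],
                 stringsAsFactors = FALSE)
    }))
    oracle <- oracle[oracle$score > 0, ]
    oracle <- oracle[order(-oracle$score, oracle$is_comp, oracle$model, oracle$entity), ]
    expect_identical(df$entity, oracle$entity)
    expect_equal(df$score, oracle$score)
  }
})

test_that("an entity matching a superset of slots never ranks below a subset match", {
  set.seed(88)
  tm <- fixture_terms()
  for (rep in 1:20) {
    sup <- composite_annotation(
      target = model_entity("a.cellml", "c", "v1"),
      property = tm$flux, chemical = tm$sodium,
      sink_location = list(tm$cytosol), mediator = tm$nhe3)
    subsets <- list(
      composite_annotation(model_entity("b.cellml", "c", "v2"),
                           property = tm$flux, chemical = tm$sodium),
      composite_annotation(model_entity("c.cellml", "c", "v3"),
                           property = tm$concentration, chemical = tm$sodium,
                           located_in = list(tm$cytosol)))
    corpus <- corpus_of(c(list(sup), subsets))
    dict <- mini_dictionary()
    res <- as.data.frame(search_corpus(corpus, dict, "sodium flux in cytosol"))
    expect_identical(res$entity[1], "a.cellml#c.v1")
  }
})

test_that("adding an unrelated model preserves the relative order of results", {
  set.seed(99)
  annotations <- lapply(1:12, function(i) random_annotation())
  annotations <- annotations[!duplicated(vapply(annotations, function(a)
    construct_entity_uri(a$target), ""))]
  dict <- mini_dictionary()
  base <- corpus_of(annotations)
  res_base <- as.data.frame(search_corpus(base, dict, "flux of sodium"))
  tm <- fixture_terms()
  unrelated <- composite_annotation(
    target = model_entity("zzz_unrelated.cellml", "c", "v"),
    property = tm$concentration, chemical = tm$potassium,
    located_in = list(tm$interstitial_fluid))
  extended <- corpus_of(c(annotations, list(unrelated)))
  res_ext <- as.data.frame(search_corpus(extended, dict, "flux of sodium"))
  kept <- res_ext$entity[res_ext$entity %in% res_base$entity]
  expect_identical(kept, res_base$entity)
})

test_that("search is deterministic for fixed corpus, dictionary and query", {
  corpus <- mini_corpus()
  dict <- mini_dictionary()
  r1 <- search_corpus(corpus, dict, "flux of sodium")
  r2 <- search_corpus(corpus, dict, "flux of sodium")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
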