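test_that("CellML parsing returns exact component and variable counts", {
  path <- withr::local_tempfile(fileext = ".cellml")
  write_minimal_cellml(path, components = list(C = character()))
  m <- read_cellml(path)
  expect_identical(nrow(m$components), 1L)
  expect_identical(nrow(m$variables), 0L)

  # generator-configured counts: c components with v variables each
  path2 <- withr::local_tempfile(fileext = ".cellml")
  comps <- setNames(lapply(1:3, function(i) paste0("v", 1:4)), paste0("comp", 1:3))
  write_minimal_cellml(path2, components = comps)
  m2 <- read_cellml(path2)
  expect_identical(nrow(m2$components), 3L)
  expect_identical(nrow(m2$variables), 12L)
  expect_identical(m2$variables$metadata_id[1], "comp1.v1")
})

test_that("malformed and unsupported documents fail with diagnostic errors", {
  bad <- withr::local_tempfile(fileext = ".cellml")
  writeLines("<model><unclosed>", bad)
  expect_error(read_cellml(bad), class = "semdisc_parse_error")

  v2 <- withr::local_tempfile(fileext = ".cellml")
  writeLines(c("<?xml version=\"1.0\"?>",
               "<model name=\"m\" xmlns=\"http://www.cellml.org/cellml/2.0#\"/>"), v2)
  err <- expect_error(read_cellml(v2), class = "semdisc_unsupported_dialect")
  expect_match(conditionMessage(err), "2.0")

  other <- withr::local_tempfile(fileext = ".cellml")
  writeLines("<model xmlns=\"http://example.org/not-cellml\"/>", other)
  err2 <- expect_error(read_cellml(other), class = "semdisc_unsupported_dialect")
  expect_match(conditionMessage(err2), "not-cellml")
})

test_that("parsing is insensitive to sibling element order", {
  p1 <- withr::local_tempfile(fileext = ".cellml")
  p2 <- withr::local_tempfile(fileext = ".cellml")
  write_minimal_cellml(p1, components = list(a = c("x", "y"), b = "z"))
  write_minimal_cellml(p2, components = list(b = "z", a = c("y", "x")))
  m1 <- read_cellml(p1); m2 <- read_cellml(p2)
  sort_df <- function(df) { df <- df[do.call(order, df), , drop = FALSE]; rownames(df) <- NULL; df }
  expect_identical(sort_df(m1$components), sort_df(m2$components))
  expect_identical(sort_df(m1$variables), sort_df(m2$variables))
})

test_that("RDF documents round-trip through both dialects", {
  set.seed(404)
  for (dialect in c("turtle", "rdfxml")) {
    for (rep in 1:5) {
      g <- random_graph(40)
      # add a blank-node chain to exercise node handling
      g <- rbind(g, rdf_triples(
        c("https://example.org/s/s1", "_:c1", "_:c1"),
        paste0("https://example.org/p/p", c(1, 2, 3)),
        c("_:c1", "lit one", "https://example.org/o/o1")))
      path <- withr::local_tempfile(fileext = if (dialect == "turtle") ".ttl" else ".rdf")
      write_annotation_graph(g, path, dialect = dialect)
      back <- read_annotation_graph(path, dialect = dialect)
      expect_true(graphs_isomorphic(g, back))
    }
  }
})

test_that("serialization is deterministic and byte-stable", {
  set.seed(405)
  g <- random_graph(30)
  p1 <- withr::local_tempfile(fileext = ".ttl")
  p2 <- withr::local_tempfile(fileext = ".ttl")
  write_annotation_graph(g, p1)
  write_annotation_graph(g[sample.int(nrow(g)), ], p2) # shuffled input rows
  expect_identical(readLines(p1), readLines(p2))
  # write -> read -> write is stable
  p3 <- withr::local_tempfile(fileext = ".ttl")
  write_annotation_graph(read_annotation_graph(p1), p3)
  expect_identical(readLines(p1), readLines(p3))
})

test_that("blank nodes from different documents stay distinct after merge", {
  t1 <- rdf_triples("_:b1", "https://example.org/p/1", "https://example.org/o/1")
  t2 <- rdf_triples("_:b1", "https://example.org/p/1", "https://example.org/o/2")
  p1 <- withr::local_tempfile(fileext = ".ttl")
  p2 <- withr::local_tempfile(fileext = ".ttl")
  write_annotation_graph(t1, p1); write_annotation_graph(t2, p2)
  merged <- read_annotation_graph(c(p1, p2))
  expect_identical(nrow(merged), 2L)
  expect_identical(length(unique(merged$s)), 2L)
})

test_that("an empty document yields an empty triple set", {
  p <- withr::local_tempfile(fileext = ".ttl")
  write_annotation_graph(rdf_triples(), p)
  expect_identical(nrow(read_annotation_graph(p)), 0L)
  # the document still declares its prefixes
  expect_true(any(grepl("^@prefix", readLines(p))))
})

test_that("the sodium-flux annotation graph decodes to its printed text", {
  a <- example_nhe3_annotation()
  triples <- encode_annotations(list(a))
  corpus <- extract_annotations(
    data.frame(file = "weinstein_1995.cellml", name = "NHE3 model"), triples)
  expect_length(corpus$annotations, 1L)
  expect_identical(
    render_description(corpus$annotations[[1]]),
    "sodium flux from proximal tubule to epithelial cell cytosol via sodium/hydrogen exchanger 3")
})

test_that("graphs without entity subjects decode to zero annotations", {
  g <- random_graph(20)
  corpus <- extract_annotations(data.frame(file = "m.cellml", name = "m"), g)
  expect_length(corpus$annotations, 0L)
})

test_that("annotation sets survive encode/write/read/extract exactly", {
  set.seed(505)
  for (rep in 1:5) {
    k <- sample(3:12, 1)
    annotations <- lapply(seq_len(k), function(i) random_annotation())
    # distinct targets to keep one annotation per entity
    annotations <- annotations[!duplicated(vapply(annotations, function(a)
      construct_entity_uri(a$target), ""))]
    corpus <- corpus_of(annotations)
    for (dialect in c("turtle", "rdfxml")) {
      path <- withr::local_tempfile(fileext = if (dialect == "turtle") ".ttl" else ".rdf")
      write_annotation_graph(encode_annotations(corpus), path, dialect = dialect)
      back <- extract_annotations(corpus$models, read_annotation_graph(path, dialect = dialect))
      expect_identical(annotation_set_signature(back$annotations),
                       annotation_set_signature(corpus$annotations))
    }
  }
})

test_that("invalid annotation subgraphs warn per entity instead of failing", {
  voc <- semdisc:::default_vocabulary()
  # process and state locations on the same entity violate the model
  g <- rdf_triples(
    s = rep("m.cellml#c.v", 3),
    p = c(voc[["property"]], voc[["source"]], voc[["located_in"]]),
    o = c("https://example.org/onto/OPB_00593", "_:a", "_:b"),
    o_type = c("iri", "blank", "blank"))
  g <- rbind(g, rdf_triples(
    c("_:a", "_:b"), rep(voc[["refers_to"]], 2),
    c("https://example.org/onto/FMA_66836", "https://example.org/onto/FMA_66768")))
  expect_warning(
    corpus <- extract_annotations(data.frame(file = "m.cellml", name = "m"), g),
    class = "semdisc_annotation_warning")
  expect_length(corpus$annotations, 0L)
})

test_that("in-file RDF blocks resolve fragments against the model file", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "inline.cellml")
  voc <- semdisc:::default_vocabulary()
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<model name=\"inline\" xmlns=\"http://www.cellml.org/cellml/1.0#\"",
    "       xmlns:cmeta=\"http://www.cellml.org/metadata/1.0#\"",
    "       xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "       xmlns:semsim=\"http://bhi.washington.edu/SemSim#\"",
    "       xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\">",
    "  <component name=\"c\" cmeta:id=\"c\">",
    "    <variable name=\"v\" units=\"dimensionless\" cmeta:id=\"c.v\"/>",
    "  </component>",
    "  <rdf:RDF>",
    "    <rdf:Description rdf:about=\"#c.v\">",
    "      <semsim:hasPhysicalProperty rdf:resource=\"https://example.org/onto/OPB_00340\"/>",
    "      <semsim:hasPhysicalEntity rdf:resource=\"https://example.org/onto/CHEBI_29101\"/>",
    "    </rdf:Description>",
    "    <rdf:Description rdf:about=\"https://example.org/onto/OPB_00340\">",
    "      <rdfs:label>concentration</rdfs:label>",
    "    </rdf:Description>",
    "    <rdf:Description rdf:about=\"https://example.org/onto/CHEBI_29101\">",
    "      <rdfs:label>sodium</rdfs:label>",
    "    </rdf:Description>",
    "  </rdf:RDF>",
    "</model>"), path)
  corpus <- ingest_corpus(dir)
  expect_length(corpus$annotations, 1L)
  expect_identical(names(corpus$index$by_entity), "inline.cellml#c.v")
  expect_identical(render_description(corpus$annotations[[1]]), "sodium concentration")
})
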