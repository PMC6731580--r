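# Shared generated corpora: building the epithelial-mini fixture once per
# test run keeps the suite fast while every test still consumes
# generator-produced data.

mini_corpus_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "epithelial-mini")
      generate_corpus(corpus_spec(), dir)
    }
    dir
  }
})

mini_corpus <- local({
  corpus <- NULL
  function() {
    if (is.null(corpus)) corpus <<- ingest_corpus(mini_corpus_dir())
    corpus
  }
})

mini_dictionary <- function() {
  read_dictionary(file.path(mini_corpus_dir(), "dictionary.tsv"))
}

write_minimal_cellml <- function(path, model_name = "m",
                                 components = list(C = character())) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<model name=\"", model_name, "\"",
                    " xmlns=\"http://www.cellml.org/cellml/1.0#\"",
                    " xmlns:cmeta=\"http://www.cellml.org/metadata/1.0#\">"))
  for (comp in names(components)) {
    lines <- c(lines, paste0("  <component name=\"", comp, "\" cmeta:id=\"", comp, "\">"))
    for (v in components[[comp]]) {
      lines <- c(lines, paste0("    <variable name=\"", v,
                               "\" units=\"dimensionless\" cmeta:id=\"",
                               comp, ".", v, "\"/>"))
    }
    lines <- c(lines, "  </component>")
  }
  writeLines(c(lines, "</model>"), path)
  path
}
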