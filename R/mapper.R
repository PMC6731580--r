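# Dictionary-based mapping of free-text query tokens to reference ontology
# terms. Matching is exact on normalized keys (the static-dictionary
# approach); there is no fuzzy matching, spelling correction or synonym
# expansion. Multi-word dictionary keys are tried greedily, longest phrase
# first, before single tokens.

DEFAULT_STOPWORDS <- c("of", "in", "the", "a", "an", "to", "from")

#' Tokenize free query text
#'
#' Lowercases, splits on whitespace and punctuation, and drops stopwords.
#'
#' @param text Query string.
#' @param stopwords Words removed after splitting.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("flux of sodium") # "flux" "sodium"
#' @export
tokenize <- function(text, stopwords = DEFAULT_STOPWORDS) {
  if (is.null(text) || length(text) == 0L || is.na(text[1])) return(character())
  toks <- strsplit(tolower(text[1]), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% stopwords]
}

normalize_key <- function(key) {
  key <- tolower(trimws(key))
  gsub("[[:space:]]+", " ", key)
}

#' Load a term-mapping dictionary
#'
#' One record per line: `key<TAB>prefix:id<TAB>uri`, with an optional fourth
#' column holding a human-readable label; `#` starts a comment. A key may
#' appear on several lines, in which case it maps to a list of terms.
#'
#' @param path Path to the dictionary file.
#' @param registry Prefix registry used to classify the term IRIs.
#' @return An object of class `term_dictionary`: a named list mapping
#'   normalized keys to lists of [ontology_term()]s.
#' @export
read_dictionary <- function(path, registry = default_prefix_registry()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) abort_parse(paste0("malformed dictionary line: '", line, "'"),
                                        file = path)
    key <- normalize_key(parts[1])
    term <- ontology_term(parts[3], label = if (length(parts) >= 4L) parts[4],
                          registry = registry)
    entries[[key]] <- c(entries[[key]], list(term))
  }
  structure(entries, class = "term_dictionary")
}

#' Write a dictionary back to its file format
#'
#' `write_dictionary()` followed by [read_dictionary()] is the identity on
#' dictionary content.
#'
#' @param dict A `term_dictionary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  lines <- character()
  for (key in sort(names(dict))) {
    for (term in dict[[key]]) {
      curie <- paste0(term$prefix, ":", basename_uri(term$uri))
      lines <- c(lines, paste(c(key, curie, term$uri, term$label %||% NULL),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

basename_uri <- function(uri) sub("^.*[/#:]", "", uri)

#' Map query tokens onto dictionary terms
#'
#' Multi-word keys are matched greedily, longest phrase first, consuming
#' their tokens; remaining tokens are looked up individually. Every token is
#' accounted for exactly once, either in `hits` or in `unmapped`.
#'
#' @param dict A `term_dictionary`.
#' @param tokens Character vector from [tokenize()].
#' @return A list of class `mapping_result` with `hits` (data-frame-like
#'   list of token / term pairs) and `unmapped` (character vector).
#' @export
map_tokens <- function(dict, tokens) {
  hits <- list()
  unmapped <- character()
  max_len <- max(c(1L, lengths(strsplit(names(dict), " ", fixed = TRUE))))
  i <- 1L
  while (i <= length(tokens)) {
    matched <- FALSE
    for (len in seq(min(max_len, length(tokens) - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (!is.null(dict[[key]])) {
        for (term in dict[[key]]) {
          hits[[length(hits) + 1L]] <- list(token = key, term = term)
        }
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      unmapped <- c(unmapped, tokens[i])
      i <- i + 1L
    }
  }
  structure(list(hits = hits, unmapped = unmapped), class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(length(x$hits), "mapped term(s);",
      length(x$unmapped), "unmapped token(s)\n")
  for (h in x$hits) cat("  ", h$token, " -> <", h$term$uri, ">\n", sep = "")
  if (length(x$unmapped) > 0L) cat("  unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  invisible(x)
}

# --- label cache -----------------------------------------------------------

#' Label cache with optional remote lookup
#'
#' Resolves term IRIs to human-readable labels, cache first. A resolver
#' function implementing the lookup-service contract (IRI in, label string
#' out) may be attached; it is only consulted on a cache miss, and its
#' results populate the cache. Remote lookup is off by default so nothing in
#' the package touches the network unless explicitly configured.
#'
#' @param resolver Optional function `uri -> label` (e.g. an OLS-style HTTP
#'   client); `NULL` disables remote lookup.
#' @return An object of class `label_cache`.
#' @export
label_cache <- function(resolver = NULL) {
  env <- new.env(parent = emptyenv())
  env$labels <- new.env(parent = emptyenv())
  env$resolver <- resolver
  env$lookups <- 0L
  structure(list(env = env), class = "label_cache")
}

#' @rdname label_cache
#' @param cache A `label_cache`.
#' @param uri Term IRI.
#' @param label Label string to store.
#' @export
label_put <- function(cache, uri, label) {
  assign(uri, label, envir = cache$env$labels)
  invisible(cache)
}

#' Resolve a term IRI to its label
#'
#' @param uri Term IRI.
#' @param cache A [label_cache()].
#' @return The label string. Raises an unresolved-label error (naming the
#'   IRI) on a miss with no resolver, and a lookup error if the resolver
#'   itself fails.
#' @export
label_for <- function(uri, cache) {
  hit <- get0(uri, envir = cache$env$labels, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (is.null(cache$env$resolver)) abort_unresolved_label(uri)
  cache$env$lookups <- cache$env$lookups + 1L
  label <- tryCatch(cache$env$resolver(uri), error = function(e) {
    abort_lookup(paste0("label lookup failed for <", uri, ">: ",
                        conditionMessage(e)), uri = uri)
  })
  if (is.null(label) || is.na(label)) abort_unresolved_label(uri)
  label_put(cache, uri, label)
  label
}

#' @rdname label_cache
#' @export
label_lookup_count <- function(cache) cache$env$lookups

#' Persist / reload a label cache as a two-column TSV
#' @param cache A `label_cache`.
#' @param path File path.
#' @export
write_label_cache <- function(cache, path) {
  uris <- sort(ls(cache$env$labels))
  lines <- vapply(uris, function(u) paste(u, get(u, envir = cache$env$labels), sep = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_label_cache
#' @param resolver Optional resolver for the reloaded cache.
#' @export
read_label_cache <- function(path, resolver = NULL) {
  cache <- label_cache(resolver)
  if (file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L) label_put(cache, parts[1], parts[2])
    }
  }
  cache
}

#' An OLS-style HTTP resolver for use with [label_cache()]
#'
#' Implements the lookup-service wire contract: HTTP GET by double-encoded
#' term IRI, JSON response carrying the label. Only used when a cache is
#' explicitly constructed with it.
#'
#' @param base_url Service base URL.
#' @return A resolver function `uri -> label`.
#' @export
ols_resolver <- function(base_url = "https://www.ebi.ac.uk/ols4/api/terms") {
  function(uri) {
    enc <- utils::URLencode(utils::URLencode(uri, reserved = TRUE), reserved = TRUE)
    con <- url(paste0(base_url, "?iri=", enc))
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    res <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE), collapse = ""),
                              simplifyVector = FALSE)
    terms <- res[["_embedded"]][["terms"]]
    if (length(terms) == 0L) return(NULL)
    terms[[1]][["label"]]
  }
}
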