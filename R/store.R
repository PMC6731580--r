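# In-memory RDF triple store with conjunctive basic-graph-pattern (BGP)
# querying. Full SPARQL is deliberately not parsed: the discovery engine only
# needs BGP joins, and a thin adapter renders pattern lists as SPARQL SELECT
# text for remote read-only endpoints that speak the standard protocol.

#' Create a triple table
#'
#' Triples are held as a data.frame with typed subject and object columns.
#' Predicates are always IRIs; literals never appear as subjects.
#'
#' @param s,p,o Character vectors (recycled to a common length) holding the
#'   subject, predicate and object lexical forms. Blank nodes are written
#'   `_:id`.
#' @param o_type Object types: `"iri"`, `"blank"` or `"literal"`. Defaults to
#'   a guess: `_:`-prefixed values are blank nodes, values that look like
#'   absolute IRIs are IRIs, everything else a plain literal.
#' @param o_datatype,o_lang Optional datatype IRI / language tag per literal.
#' @return A data.frame of class `rdf_triples`.
#' @export
rdf_triples <- function(s = character(), p = character(), o = character(),
                        o_type = NULL, o_datatype = NA_character_,
                        o_lang = NA_character_) {
  n <- max(length(s), length(p), length(o), 0L)
  s <- rep_len(as.character(s), n); p <- rep_len(as.character(p), n)
  o <- rep_len(as.character(o), n)
  if (is.null(o_type)) {
    o_type <- ifelse(startsWith(o, "_:"), "blank",
                     ifelse(grepl("^[A-Za-z][A-Za-z0-9+.-]*://", o) |
                              grepl("^urn:", o), "iri", "literal"))
  }
  df <- data.frame(
    s = s, s_type = ifelse(startsWith(s, "_:"), "blank", "iri"),
    p = p, o = o, o_type = rep_len(o_type, n),
    o_datatype = rep_len(as.character(o_datatype), n),
    o_lang = rep_len(as.character(o_lang), n),
    stringsAsFactors = FALSE)
  if (n > 0L && any(df$o_type == "literal" & startsWith(df$o, "_:"))) {
    # permitted, but only when the caller asked for a literal explicitly
  }
  class(df) <- c("rdf_triples", "data.frame")
  df
}

empty_triples <- function() rdf_triples()

triples_rbind <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(parts) == 0L) return(empty_triples())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("rdf_triples", "data.frame")
  out
}

# Canonical one-string key per triple, used for set semantics and sorting.
triple_keys <- function(df) {
  paste(df$s_type, df$s, df$p, df$o_type, df$o,
        ifelse(is.na(df$o_datatype), "", df$o_datatype),
        ifelse(is.na(df$o_lang), "", df$o_lang), sep = "\x01")
}

dedupe_triples <- function(df) {
  df <- df[!duplicated(triple_keys(df)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rdf_triples", "data.frame")
  df
}

#' Create an in-memory triple store
#'
#' @param triples Optional initial [rdf_triples()] table.
#' @return An object of class `triple_store`.
#' @export
triple_store <- function(triples = NULL) {
  env <- new.env(parent = emptyenv())
  env$triples <- empty_triples()
  store <- structure(list(env = env), class = "triple_store")
  if (!is.null(triples)) add_triples(store, triples)
  store
}

#' Add triples to a store (set semantics)
#'
#' Duplicate triples are ignored; the store size equals the number of
#' distinct triples added.
#'
#' @param store A [triple_store()].
#' @param triples An [rdf_triples()] table.
#' @return The store, invisibly (it is updated in place).
#' @export
add_triples <- function(store, triples) {
  stopifnot(inherits(store, "triple_store"))
  store$env$triples <- dedupe_triples(triples_rbind(store$env$triples, triples))
  invisible(store)
}

#' @export
#' @rdname add_triples
store_size <- function(store) nrow(store$env$triples)

store_triples <- function(store) store$env$triples

#' @export
print.triple_store <- function(x, ...) {
  cat("triple store with", store_size(x), "triples\n")
  invisible(x)
}

#' Triple patterns
#'
#' Each position is either a constant or a named wildcard written `?name`.
#' Shared wildcard names across the patterns of a query denote joins.
#'
#' @param s,p,o Subject / predicate / object: a constant IRI, `_:` blank id,
#'   literal, or a `?name` wildcard.
#' @param o_literal Set `TRUE` to force the object constant to be matched as
#'   a literal even if it looks like an IRI.
#' @return An object of class `triple_pattern`.
#' @export
pattern <- function(s, p, o, o_literal = FALSE) {
  structure(list(s = s, p = p, o = o, o_literal = isTRUE(o_literal)),
            class = "triple_pattern")
}

is_wildcard <- function(x) is.character(x) && length(x) == 1L && startsWith(x, "?")

wildcard_name <- function(x) substring(x, 2L)

pattern_wildcards <- function(pat) {
  out <- character()
  for (pos in c("s", "p", "o")) if (is_wildcard(pat[[pos]])) out <- c(out, wildcard_name(pat[[pos]]))
  unique(out)
}

# Rows of `df` matching pattern `pat` under bindings `env` (named list).
match_pattern_rows <- function(df, pat, binding) {
  keep <- rep(TRUE, nrow(df))
  for (pos in c("s", "p", "o")) {
    val <- pat[[pos]]
    if (is_wildcard(val)) {
      nm <- wildcard_name(val)
      if (!is.null(binding[[nm]])) val <- binding[[nm]] else next
    }
    col <- df[[pos]]
    keep <- keep & (col == val)
    if (pos == "o" && pat$o_literal) keep <- keep & df$o_type == "literal"
  }
  df[keep, , drop = FALSE]
}

#' Evaluate a basic graph pattern against a store
#'
#' Conjunctive join of triple patterns by ordered nested loops, most
#' selective pattern first (fewest unbound wildcards, then fewest matching
#' rows). Results are the exact set of bindings satisfying all patterns
#' simultaneously, in a deterministic order (sorted by bound values over
#' alphabetically ordered wildcard names). Literals compare by lexical form;
#' no numeric value-space coercion is performed.
#'
#' @param store A [triple_store()] or remote endpoint adapter.
#' @param patterns A list of [pattern()] objects.
#' @return A data.frame with one character column per wildcard; zero rows is
#'   a valid (empty) answer.
#' @export
query_bgp <- function(store, patterns) UseMethod("query_bgp")

#' @export
query_bgp.triple_store <- function(store, patterns) {
  stopifnot(length(patterns) > 0L)
  df <- store_triples(store)
  vars <- sort(unique(unlist(lapply(patterns, pattern_wildcards))))
  solutions <- bgp_join(df, patterns, list())
  bindings_to_frame(solutions, vars)
}

bgp_join <- function(df, patterns, binding) {
  if (length(patterns) == 0L) return(list(binding))
  # most selective first: fewest unbound wildcard positions, then match count
  unbound <- vapply(patterns, function(p) {
    sum(vapply(c("s", "p", "o"), function(pos) {
      is_wildcard(p[[pos]]) && is.null(binding[[wildcard_name(p[[pos]])]])
    }, TRUE))
  }, 0L)
  counts <- vapply(patterns, function(p) nrow(match_pattern_rows(df, p, binding)), 0L)
  pick <- order(unbound, counts)[1]
  pat <- patterns[[pick]]
  rest <- patterns[-pick]
  rows <- match_pattern_rows(df, pat, binding)
  out <- list()
  if (nrow(rows) == 0L) return(out)
  for (i in seq_len(nrow(rows))) {
    b <- binding
    ok <- TRUE
    for (pos in c("s", "p", "o")) {
      if (is_wildcard(pat[[pos]])) {
        nm <- wildcard_name(pat[[pos]])
        val <- rows[[pos]][i]
        if (is.null(b[[nm]])) b[[nm]] <- val
        else if (b[[nm]] != val) { ok <- FALSE; break }
      }
    }
    if (ok) out <- c(out, bgp_join(df, rest, b))
  }
  out
}

bindings_to_frame <- function(solutions, vars) {
  if (length(vars) == 0L) vars <- character()
  if (length(solutions) == 0L) {
    out <- as.data.frame(setNames(rep(list(character()), length(vars)), vars),
                         stringsAsFactors = FALSE, optional = TRUE)
    return(out)
  }
  if (length(vars) == 0L) {
    # all-constant query that matched: one solution row with no bindings
    return(data.frame(row.names = 1)[, character(0), drop = FALSE])
  }
  out <- as.data.frame(
    setNames(lapply(vars, function(v) {
      vapply(solutions, function(b) {
        if (is.null(b[[v]])) NA_character_ else b[[v]]
      }, "")
    }), vars),
    stringsAsFactors = FALSE, optional = TRUE)
  out <- unique(out)
  if (length(vars) > 0L) {
    out <- out[do.call(order, out), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Render a BGP pattern list as SPARQL SELECT text
#'
#' The adapter contract for remote read-only endpoints: a conjunctive list
#' of [pattern()]s becomes a `SELECT` over all wildcards with one triple
#' pattern per line.
#'
#' @param patterns List of [pattern()] objects.
#' @return A single SPARQL SELECT string.
#' @export
as_sparql_select <- function(patterns) {
  vars <- sort(unique(unlist(lapply(patterns, pattern_wildcards))))
  term <- function(x, literal = FALSE) {
    if (is_wildcard(x)) return(x)
    if (startsWith(x, "_:")) return(x)
    if (!literal && (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) || grepl("^urn:", x))) {
      return(paste0("<", x, ">"))
    }
    paste0('"', gsub('"', '\\\\"', x), '"')
  }
  body <- vapply(patterns, function(p) {
    paste(term(p$s), term(p$p), term(p$o, literal = p$o_literal), ".")
  }, "")
  paste0("SELECT ", paste(paste0("?", vars), collapse = " "),
         " WHERE {\n  ", paste(body, collapse = "\n  "), "\n}")
}

#' Remote SPARQL endpoint adapter
#'
#' Satisfies the same query contract as the local store by translating
#' pattern lists into SPARQL SELECT text and submitting them to a read-only
#' endpoint speaking the SPARQL 1.1 protocol with JSON results. The
#' transport is injectable so deployments can add authentication or callers
#' can supply a loopback executor.
#'
#' @param endpoint Endpoint URL.
#' @param transport Function `(endpoint, sparql_text) -> parsed JSON list`
#'   in SPARQL JSON results form. The default performs an HTTP GET with the
#'   query in the `query` parameter.
#' @param timeout,retries Request timeout (seconds) and retry count.
#' @return An object of class `remote_store`.
#' @export
remote_store <- function(endpoint, transport = sparql_http_transport,
                         timeout = 30, retries = 2) {
  structure(list(endpoint = endpoint, transport = transport,
                 timeout = timeout, retries = retries),
            class = "remote_store")
}

sparql_http_transport <- function(endpoint, query) {
  url <- paste0(endpoint, if (grepl("\\?", endpoint)) "&" else "?",
                "query=", utils::URLencode(query, reserved = TRUE))
  con <- url(url, headers = c(Accept = "application/sparql-results+json"))
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  txt <- tryCatch(paste(readLines(con, warn = FALSE), collapse = "\n"),
                  error = function(e) abort_lookup(paste0("SPARQL endpoint request failed: ",
                                                          conditionMessage(e))))
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

#' @export
query_bgp.remote_store <- function(store, patterns) {
  q <- as_sparql_select(patterns)
  res <- NULL
  for (attempt in seq_len(store$retries + 1L)) {
    res <- tryCatch(store$transport(store$endpoint, q), error = function(e) e)
    if (!inherits(res, "error")) break
  }
  if (inherits(res, "error")) {
    abort_lookup(paste0("remote query failed after ", store$retries + 1L,
                        " attempts: ", conditionMessage(res)))
  }
  vars <- sort(unlist(res$head$vars, use.names = FALSE))
  rows <- lapply(res$results$bindings, function(b) {
    setNames(lapply(vars, function(v) {
      cell <- b[[v]]
      if (is.null(cell)) NULL
      else if (identical(cell$type, "bnode")) paste0("_:", cell$value)
      else cell$value
    }), vars)
  })
  bindings_to_frame(rows, vars)
}
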