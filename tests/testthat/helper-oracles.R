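# Independent oracles and fixture builders used across the suite. Each
# oracle is a second, deliberately naive implementation of the operation it
# checks, sharing no code with the package internals.

# --- random fixture entities / annotations --------------------------------

random_ident <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste0(sample(letters, 1),
           paste(sample(c(letters, as.character(0:9), "_"),
                        sample(2:8, 1), replace = TRUE), collapse = ""))
  }, "")
}

random_entity <- function() {
  has_var <- runif(1) < 0.8
  model_entity(paste0(random_ident(), ".cellml"),
               random_ident(),
               if (has_var) {
                 v <- random_ident()
                 # variable names may themselves contain dots
                 if (runif(1) < 0.3) paste0(v, ".", random_ident()) else v
               })
}

fixture_term_pool <- function() {
  tm <- semdisc::fixture_terms()
  tm[!names(tm) %in% "nhe3"]
}

random_annotation <- function(entity = random_entity()) {
  tm <- semdisc::fixture_terms()
  chems <- tm[c("sodium", "hydrogen", "glucose", "potassium")]
  locs <- tm[c("apical_membrane", "basolateral_membrane", "cytosol",
               "tubule_lumen", "interstitial_fluid", "proximal_tubule",
               "epithelial_cell")]
  process <- runif(1) < 0.5
  pick_chain <- function(maxlen) {
    n <- sample.int(maxlen, 1)
    sample(locs, n)
  }
  if (process) {
    composite_annotation(
      target = entity, property = tm$flux,
      chemical = if (runif(1) < 0.8) chems[[sample.int(4, 1)]],
      source_location = if (runif(1) < 0.8) pick_chain(2) else list(),
      sink_location = pick_chain(2),
      mediator = if (runif(1) < 0.5) tm$nhe3,
      species = if (runif(1) < 0.5) "Homo sapiens",
      gene = if (runif(1) < 0.3) "SLC9A3")
  } else {
    composite_annotation(
      target = entity, property = tm$concentration,
      chemical = chems[[sample.int(4, 1)]],
      located_in = pick_chain(2),
      species = if (runif(1) < 0.5) "Rattus norvegicus")
  }
}

# corpus wrapping a set of annotations, one model per distinct file
corpus_of <- function(annotations) {
  files <- unique(vapply(annotations, function(a) a$target$model_file, ""))
  annotated_corpus(data.frame(file = files, name = files, stringsAsFactors = FALSE),
                   annotations)
}

# canonical one-line signature of an annotation, for set comparisons
annotation_signature <- function(a) {
  chain_sig <- function(chain) paste(vapply(chain, function(t) t$uri, ""), collapse = ">")
  paste(construct_entity_uri(a$target), a$property$uri,
        if (is.null(a$chemical)) "" else a$chemical$uri,
        chain_sig(a$source_location), chain_sig(a$sink_location),
        chain_sig(a$located_in),
        if (is.null(a$mediator)) "" else a$mediator$uri,
        a$species %||% "", a$gene %||% "", sep = "|")
}

annotation_set_signature <- function(annotations) {
  sort(vapply(annotations, annotation_signature, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- straight-line template oracle for render_description -----------------

oracle_render <- function(a) {
  first_label <- function(chain) chain[[1]]$label
  words <- character()
  if (!is.null(a$chemical)) words <- c(words, a$chemical$label)
  words <- c(words, a$property$label)
  if (length(a$source_location) > 0 || length(a$sink_location) > 0) {
    if (length(a$source_location) > 0) words <- c(words, "from", first_label(a$source_location))
    if (length(a$sink_location) > 0) words <- c(words, "to", first_label(a$sink_location))
    if (!is.null(a$mediator)) words <- c(words, "via", a$mediator$label)
  } else {
    if (length(a$located_in) > 0) words <- c(words, "in", first_label(a$located_in))
    if (!is.null(a$mediator)) words <- c(words, "via", a$mediator$label)
  }
  paste(words, collapse = " ")
}

# --- BGP join oracles ------------------------------------------------------

# vectorized relational oracle: per-pattern solution tables joined by merge()
oracle_bgp_merge <- function(triples, patterns) {
  df <- as.data.frame(triples)
  vars <- sort(unique(unlist(lapply(patterns, function(p) {
    unlist(lapply(c("s", "p", "o"), function(pos) {
      v <- p[[pos]]
      if (is.character(v) && startsWith(v, "?")) substring(v, 2)
    }))
  }))))
  empty <- function() {
    out <- as.data.frame(setNames(rep(list(character()), length(vars)), vars),
                         optional = TRUE)
    out
  }
  tabs <- list()
  for (p in patterns) {
    keep <- rep(TRUE, nrow(df))
    cols <- list() # wildcard name -> positions where it appears
    for (pos in c("s", "p", "o")) {
      v <- p[[pos]]
      if (is.character(v) && startsWith(v, "?")) {
        nm <- substring(v, 2)
        cols[[nm]] <- c(cols[[nm]], pos)
      } else {
        keep <- keep & df[[pos]] == v
      }
    }
    sub <- df[keep, , drop = FALSE]
    # repeated wildcard within one pattern: positions must agree
    for (nm in names(cols)) {
      if (length(cols[[nm]]) > 1) {
        agree <- Reduce(`&`, lapply(cols[[nm]][-1], function(pos) {
          sub[[pos]] == sub[[cols[[nm]][1]]]
        }))
        sub <- sub[agree, , drop = FALSE]
      }
    }
    if (length(cols) == 0) {
      # all-constant pattern: acts as a guard
      if (nrow(sub) == 0) return(empty())
      next
    }
    if (nrow(sub) == 0) return(empty())
    tabs[[length(tabs) + 1]] <- unique(as.data.frame(
      setNames(lapply(cols, function(pos) sub[[pos[1]]]), names(cols)),
      optional = TRUE, stringsAsFactors = FALSE))
  }
  if (length(tabs) == 0) {
    # only guards, all satisfied: one empty binding
    return(data.frame(row.names = 1)[, character(0), drop = FALSE])
  }
  cross_join <- function(x, y) {
    ix <- rep(seq_len(nrow(x)), each = max(nrow(y), 0))
    iy <- rep(seq_len(nrow(y)), times = max(nrow(x), 0))
    out <- cbind(x[ix, , drop = FALSE], y[iy, , drop = FALSE])
    rownames(out) <- NULL
    out
  }
  res <- Reduce(function(x, y) {
    common <- intersect(names(x), names(y))
    if (length(common) == 0) cross_join(x, y) else merge(x, y, by = common)
  }, tabs)
  if (nrow(res) == 0) return(empty())
  res <- unique(res[, vars, drop = FALSE])
  if (length(vars) > 0) res <- res[do.call(order, res), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# fully exhaustive oracle: try every combination of triple rows
oracle_bgp_exhaustive <- function(triples, patterns) {
  df <- as.data.frame(triples)
  n <- nrow(df)
  k <- length(patterns)
  sols <- list()
  combos <- expand.grid(rep(list(seq_len(n)), k))
  for (r in seq_len(nrow(combos))) {
    binding <- list()
    ok <- TRUE
    for (pi in seq_len(k)) {
      row <- df[combos[r, pi], ]
      for (pos in c("s", "p", "o")) {
        v <- patterns[[pi]][[pos]]
        if (is.character(v) && startsWith(v, "?")) {
          nm <- substring(v, 2)
          if (is.null(binding[[nm]])) binding[[nm]] <- row[[pos]]
          else if (binding[[nm]] != row[[pos]]) { ok <- FALSE; break }
        } else if (row[[pos]] != v) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) sols[[length(sols) + 1]] <- binding
  }
  vars <- sort(unique(unlist(lapply(sols, names))))
  if (length(sols) == 0) {
    vars <- sort(unique(unlist(lapply(patterns, function(p) {
      unlist(lapply(c("s", "p", "o"), function(pos) {
        v <- p[[pos]]
        if (is.character(v) && startsWith(v, "?")) substring(v, 2)
      }))
    }))))
    return(as.data.frame(setNames(rep(list(character()), length(vars)), vars),
                         optional = TRUE))
  }
  out <- unique(as.data.frame(setNames(lapply(vars, function(v) {
    vapply(sols, function(b) b[[v]], "")
  }), vars), optional = TRUE, stringsAsFactors = FALSE))
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_graph <- function(n_triples, n_subjects = 12, n_preds = 5, n_objects = 12) {
  subs <- paste0("https://example.org/s/s", seq_len(n_subjects))
  preds <- paste0("https://example.org/p/p", seq_len(n_preds))
  objs <- c(paste0("https://example.org/o/o", seq_len(n_objects %/% 2)),
            paste0("lit", seq_len(n_objects - n_objects %/% 2)))
  rdf_triples(sample(subs, n_triples, replace = TRUE),
              sample(preds, n_triples, replace = TRUE),
              sample(objs, n_triples, replace = TRUE))
}

random_patterns <- function(triples, k = 3) {
  df <- as.data.frame(triples)
  vars <- c("?x", "?y", "?z")
  repeat {
    pats <- lapply(seq_len(k), function(i) {
      row <- df[sample.int(nrow(df), 1), ]
      mk <- function(const) if (runif(1) < 0.5) sample(vars, 1) else const
      pattern(mk(row$s), mk(row$p), mk(row$o))
    })
    n_wild <- sum(vapply(pats, function(p) {
      sum(vapply(list(p$s, p$p, p$o),
                 function(v) is.character(v) && startsWith(v, "?"), TRUE))
    }, 0L))
    if (n_wild > 0L) return(pats)
  }
}

# --- exhaustive alignment-score oracle ------------------------------------

oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -4) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1) + if (av[i] == bv[j]) match else mismatch)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# --- loopback SPARQL endpoint ---------------------------------------------

# Evaluates the SELECT text produced by as_sparql_select() against a local
# triple table using the merge oracle, and answers in SPARQL JSON form.
loopback_endpoint <- function(triples) {
  function(endpoint, query) {
    flat <- gsub("\n", " ", query)
    header <- sub("^SELECT (.*) WHERE.*$", "\\1", flat)
    vars <- substring(strsplit(trimws(header), "[[:space:]]+")[[1]], 2)
    body <- sub("^.*WHERE \\{(.*)\\}.*$", "\\1", flat)
    stmts <- strsplit(body, "[[:space:]]\\.[[:space:]]*")[[1]]
    stmts <- trimws(stmts[nzchar(trimws(stmts))])
    parse_term <- function(tok) {
      if (startsWith(tok, "<")) substr(tok, 2, nchar(tok) - 1)
      else if (startsWith(tok, "\"")) gsub("\\\"", "\"", substr(tok, 2, nchar(tok) - 1), fixed = TRUE)
      else tok
    }
    patterns <- lapply(stmts, function(s) {
      toks <- strsplit(s, "[[:space:]]+")[[1]]
      pattern(parse_term(toks[1]), parse_term(toks[2]), parse_term(toks[3]))
    })
    rows <- oracle_bgp_merge(triples, patterns)
    bindings <- lapply(seq_len(nrow(rows)), function(i) {
      setNames(lapply(vars, function(v) {
        val <- rows[[v]][i]
        if (startsWith(val, "_:")) list(type = "bnode", value = substring(val, 3))
        else if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", val)) list(type = "uri", value = val)
        else list(type = "literal", value = val)
      }), vars)
    })
    list(head = list(vars = as.list(vars)),
         results = list(bindings = bindings))
  }
}
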