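# Protein sequence retrieval and percent-identity similarity. The local
# route reads FASTA collections and computes optimal global pairwise
# alignments; the remote route implements the wire contracts of a
# dbfetch-style sequence service and a Clustal-style multiple-alignment
# service that reports a percent-identity matrix. Local mode is the default
# and never touches the network.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Protein records
#'
#' @param accession Non-empty accession string.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus `X`;
#'   uppercased on construction.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence) {
  if (is.null(accession) || !nzchar(accession)) abort_invalid_input("accession must be non-empty")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) abort_invalid_input("sequence must be non-empty")
  letters <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters, AA_ALPHABET)
  if (length(bad) > 0L) {
    abort_invalid_input(paste0("sequence of ", accession,
                               " contains non-amino-acid letters: ",
                               paste(bad, collapse = "")))
  }
  structure(list(accession = accession, sequence = sequence), class = "protein_record")
}

#' Sequence sources
#'
#' A sequence source serves [fetch_sequence()] requests. The local form
#' wraps a FASTA collection (consulted and cached first); an optional remote
#' fetcher implementing the dbfetch contract (`accession -> sequence
#' string`) is used only for accessions the local collection lacks, and its
#' hits are cached so repeated fetches never repeat a call.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences, or `NULL`.
#' @param remote_fetcher Optional function `accession -> sequence`.
#' @return An object of class `sequence_source`.
#' @export
sequence_source <- function(fasta = NULL, remote_fetcher = NULL) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$remote <- remote_fetcher
  env$calls <- 0L
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
      aa <- Biostrings::readAAStringSet(fasta)
      setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
    } else if (!is.null(names(fasta))) {
      fasta
    } else {
      abort_invalid_input("fasta must be a file path or a named character vector")
    }
    for (acc in names(seqs)) assign(acc, toupper(seqs[[acc]]), envir = env$cache)
  }
  structure(list(env = env), class = "sequence_source")
}

#' Fetch a protein sequence by accession
#'
#' @param accession Accession string.
#' @param source A [sequence_source()].
#' @return A [protein_record()].
#' @export
fetch_sequence <- function(accession, source) {
  stopifnot(inherits(source, "sequence_source"))
  hit <- get0(accession, envir = source$env$cache, inherits = FALSE)
  if (!is.null(hit)) return(protein_record(accession, hit))
  if (is.null(source$env$remote)) {
    abort_not_found(paste0("accession not found in sequence source: ", accession))
  }
  source$env$calls <- source$env$calls + 1L
  seq <- tryCatch(source$env$remote(accession), error = function(e) {
    abort_lookup(paste0("sequence fetch failed for ", accession, ": ",
                        conditionMessage(e)))
  })
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) {
    abort_not_found(paste0("accession not found: ", accession))
  }
  assign(accession, toupper(seq), envir = source$env$cache)
  protein_record(accession, seq)
}

#' @rdname fetch_sequence
#' @export
fetch_call_count <- function(source) source$env$calls

#' Optimal global pairwise alignment
#'
#' Needleman–Wunsch global alignment with linear gap penalty, computed with
#' Biostrings dynamic programming. Default scoring is match +1, mismatch 0,
#' gap -4: the gap penalty is deliberately heavy relative to a mismatch so
#' that diverged substitution-only pairs align gap-free and their percent
#' identity reflects per-site divergence rather than opportunistic
#' realignment; pass a substitution matrix for biologically calibrated
#' scoring.
#'
#' @param a,b Sequences (character strings or [protein_record()]s).
#' @param scoring A list `list(match=, mismatch=, gap=)` or a square numeric
#'   substitution matrix with residue dimnames, in which case `gap` from
#'   `gap_penalty` applies.
#' @param gap_penalty Per-position gap penalty used with a matrix scoring
#'   (negative number).
#' @return A list of class `pairwise_alignment` with `a`, `b` (aligned
#'   strings of equal length, gaps as `-`) and `score`.
#' @export
global_align <- function(a, b, scoring = list(match = 1, mismatch = 0, gap = -4),
                         gap_penalty = -4) {
  a_seq <- if (inherits(a, "protein_record")) a$sequence else toupper(as.character(a))
  b_seq <- if (inherits(b, "protein_record")) b$sequence else toupper(as.character(b))
  if (!nzchar(a_seq) || !nzchar(b_seq)) abort_invalid_input("sequences must be non-empty")
  if (is.matrix(scoring)) {
    submat <- scoring
    gap <- gap_penalty
  } else {
    letters <- unique(c(strsplit(a_seq, "")[[1]], strsplit(b_seq, "")[[1]]))
    submat <- matrix(scoring$mismatch, length(letters), length(letters),
                     dimnames = list(letters, letters))
    diag(submat) <- scoring$match
    gap <- scoring$gap
  }
  aln <- Biostrings::pairwiseAlignment(
    a_seq, b_seq, type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = -gap)
  structure(list(a = as.character(Biostrings::alignedPattern(aln)),
                 b = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "pairwise_alignment")
}

#' Percent identity of an alignment
#'
#' Identity is counted over columns where both sequences have a residue
#' (gap-excluded columns), matching the percent-identity convention of
#' Clustal-style matrices, and rounded half-up to two decimals.
#'
#' @param alignment A `pairwise_alignment` from [global_align()].
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1]]
  b <- strsplit(alignment$b, "")[[1]]
  if (length(a) != length(b)) abort_invalid_input("aligned strings differ in length")
  both <- a != "-" & b != "-"
  if (!any(both)) {
    semdisc_error("alignment has no columns where both sequences have a residue",
                  "semdisc_undefined_identity")
  }
  round_half_up(100 * sum(a[both] == b[both]) / sum(both), 2L)
}

round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' Pairwise percent-identity similarity matrix
#'
#' Aligns every pair of records globally and tabulates gap-excluded percent
#' identities. The matrix is symmetric with a diagonal of 100 and follows
#' the order of the input accessions.
#'
#' @param records A list of [protein_record()]s, a named character vector of
#'   sequences, or a [sequence_source()] plus `accessions`.
#' @param accessions When `records` is a sequence source, which accessions
#'   to include.
#' @param scoring Passed to [global_align()].
#' @return An object of class `similarity_matrix`: a numeric matrix with
#'   accession dimnames.
#' @export
similarity_matrix <- function(records, accessions = NULL,
                              scoring = list(match = 1, mismatch = 0, gap = -4)) {
  if (inherits(records, "sequence_source")) {
    stopifnot(!is.null(accessions))
    records <- lapply(accessions, fetch_sequence, source = records)
  }
  if (is.character(records)) {
    records <- mapply(protein_record, names(records), records, SIMPLIFY = FALSE)
  }
  accs <- vapply(records, `[[`, "", "accession")
  if (length(accs) < 2L) abort_invalid_input("at least two records are required")
  if (anyDuplicated(accs)) abort_invalid_input("duplicate accessions in input")
  n <- length(accs)
  m <- matrix(100, n, n, dimnames = list(accs, accs))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pid <- percent_identity(global_align(records[[i]], records[[j]], scoring))
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("percent-identity matrix over", nrow(x), "proteins\n")
  print(unclass(x))
  invisible(x)
}

#' Parse a Clustal-style percent-identity matrix
#'
#' The multiple-alignment service's `pim` text format: an optional `#`
#' header, then one line per sequence, `index: accession pid pid ...`. The
#' remote similarity route submits sequences to the service and parses its
#' matrix with this function instead of aligning locally.
#'
#' @param text The matrix text (single string or vector of lines).
#' @return A `similarity_matrix`.
#' @export
parse_pim <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  accs <- character()
  rows <- list()
  for (line in lines) {
    line <- sub("^[0-9]+:\\s*", "", line)
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(parts) < 2L) abort_parse(paste0("malformed identity-matrix line: '", line, "'"))
    accs <- c(accs, parts[1])
    rows[[length(rows) + 1L]] <- suppressWarnings(as.numeric(parts[-1]))
  }
  n <- length(accs)
  if (n == 0L || any(vapply(rows, length, 1L) != n) || anyNA(unlist(rows))) {
    abort_parse("percent-identity matrix is not square numeric")
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(accs, accs)
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

#' Remote similarity route
#'
#' Submits all sequences to a multiple-alignment service and parses the
#' percent-identity matrix it returns. The service client is injectable:
#' any function taking a named character vector of sequences and returning
#' the service's matrix text satisfies the contract.
#'
#' @param records List of [protein_record()]s or named character vector.
#' @param service Function `named-sequences -> pim text`.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix_remote <- function(records, service) {
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- setNames(vapply(records, `[[`, "", "sequence"),
                     vapply(records, `[[`, "", "accession"))
  }
  if (anyDuplicated(names(seqs))) abort_invalid_input("duplicate accessions in input")
  text <- tryCatch(service(seqs), error = function(e) {
    abort_lookup(paste0("alignment service failed: ", conditionMessage(e)))
  })
  parse_pim(text)
}

#' Write protein records as FASTA
#' @param records List of [protein_record()]s or named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!is.character(records)) {
    records <- setNames(vapply(records, `[[`, "", "sequence"),
                        vapply(records, `[[`, "", "accession"))
  }
  lines <- character()
  for (acc in names(records)) {
    seq <- records[[acc]]
    starts <- seq(1L, nchar(seq), by = width)
    lines <- c(lines, paste0(">", acc),
               vapply(starts, function(s) substr(seq, s, min(s + width - 1L, nchar(seq))), ""))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
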