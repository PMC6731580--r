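test_that("protein records validate their alphabet and fields", {
  r <- protein_record("ACC1", "acdefg")
  expect_identical(r$sequence, "ACDEFG")
  expect_error(protein_record("", "ACDE"), class = "semdisc_invalid_input")
  expect_error(protein_record("ACC1", ""), class = "semdisc_invalid_input")
  expect_error(protein_record("ACC1", "ACDZ"), class = "semdisc_invalid_input")
})

test_that("sequences are fetched locally first and cached from remote", {
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(FIX001 = "ACDEFGHIKL", FIX002 = "MNPQRSTVWY"), fasta)
  src <- sequence_source(fasta)
  expect_identical(fetch_sequence("FIX001", src)$sequence, "ACDEFGHIKL")
  expect_error(fetch_sequence("NOPE", src), class = "semdisc_not_found")

  served <- new.env(); served$n <- 0L
  remote <- sequence_source(fasta, remote_fetcher = function(acc) {
    served$n <- served$n + 1L
    if (acc == "REM01") "WWWWYYYY" else NA
  })
  # local hits never call the remote
  fetch_sequence("FIX002", remote)
  expect_identical(fetch_call_count(remote), 0L)
  # remote miss -> one call, then served from cache
  expect_identical(fetch_sequence("REM01", remote)$sequence, "WWWWYYYY")
  expect_identical(fetch_sequence("REM01", remote)$sequence, "WWWWYYYY")
  expect_identical(fetch_call_count(remote), 1L)
  expect_identical(served$n, 1L)
  expect_error(fetch_sequence("GONE", remote), class = "semdisc_not_found")
})

test_that("global alignment handles the boundary cases", {
  id <- global_align("ACDE", "ACDE")
  expect_identical(id$a, "ACDE")
  expect_identical(id$b, "ACDE")
  expect_identical(id$score, 4)
  # single mismatch column beats two gaps under default scoring
  mm <- global_align("A", "G")
  expect_identical(nchar(mm$a), 1L)
  expect_identical(mm$score, 0)
  expect_error(global_align("", "ACDE"), class = "semdisc_invalid_input")
  # gaps removed recover the inputs
  set.seed(12)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "D"), sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D"), sample(2:8, 1), replace = TRUE), collapse = "")
    aln <- global_align(a, b)
    expect_identical(nchar(aln$a), nchar(aln$b))
    expect_identical(gsub("-", "", aln$a), a)
    expect_identical(gsub("-", "", aln$b), b)
  }
})

test_that("alignment scores equal exhaustive enumeration on short sequences", {
  seqs3 <- unlist(lapply(1:3, function(len) {
    apply(expand.grid(rep(list(c("A", "C", "D")), len)), 1, paste, collapse = "")
  }))
  pairs <- which(upper.tri(diag(length(seqs3)), diag = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- seqs3[pairs[k, 1]]; b <- seqs3[pairs[k, 2]]
    expect_identical(global_align(a, b)$score, oracle_align_score(a, b),
                     label = paste(a, "vs", b))
  }
})

test_that("percent identity follows the gap-excluded convention", {
  expect_identical(percent_identity(global_align("ACDE", "ACDE")), 100)
  expect_identical(percent_identity(global_align("ACDE", "ACDF")), 75)
  # disjoint alphabets at equal length: no identical columns
  expect_identical(percent_identity(global_align("ACDE", "GHIK")), 0)
  # rounding is half-up to two decimals: 1/3 identical
  aln <- structure(list(a = "AAA", b = "ACD", score = 1), class = "pairwise_alignment")
  expect_identical(percent_identity(aln), 33.33)
  # all-gap columns leave identity undefined
  degenerate <- structure(list(a = "A-", b = "-G", score = -2),
                          class = "pairwise_alignment")
  expect_error(percent_identity(degenerate), class = "semdisc_undefined_identity")
})

test_that("similarity matrices are symmetric with a 100 diagonal", {
  m <- similarity_matrix(c(P1 = "ACDEFGHIKL", P2 = "ACDEFGHIKL", P3 = "WYWYWYWYWY"))
  expect_identical(dim(m), c(3L, 3L))
  expect_true(all(diag(m) == 100))
  expect_identical(m["P1", "P2"], 100)
  expect_identical(m["P1", "P3"], 0)
  expect_true(isSymmetric(unclass(m)))
  expect_error(similarity_matrix(c(P1 = "ACDE")), class = "semdisc_invalid_input")
  expect_error(similarity_matrix(c(P1 = "ACDE", P1 = "ACDF")),
               class = "semdisc_invalid_input")
})

test_that("similarity values follow their accessions under reordering", {
  set.seed(23)
  aas <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "")
  seqs <- vapply(1:4, function(i) paste(sample(aas, 50, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("P", 1:4)
  m1 <- similarity_matrix(seqs)
  m2 <- similarity_matrix(seqs[c(3, 1, 4, 2)])
  for (i in names(seqs)) for (j in names(seqs)) {
    expect_identical(m1[i, j], m2[i, j])
  }
})

test_that("planted mutation fractions are recovered by the local route", {
  dir <- mini_corpus_dir()
  src <- sequence_source(file.path(dir, "proteins.fasta"))
  m <- similarity_matrix(src, accessions = c("FIXP000", "FIXP001", "FIXP002", "FIXP003"))
  planted <- c(90, 50, 20)
  got <- m["FIXP000", c("FIXP001", "FIXP002", "FIXP003")]
  expect_true(all(abs(got - planted) <= 2))
})

test_that("Clustal-style percent-identity matrix text parses", {
  # synthetic stand-in for the alignment service's pim format
  text <- c("# Percent Identity Matrix - created by an alignment service",
            "",
            "  1: SEQA  100.00   62.50   12.00",
            "  2: SEQB   62.50  100.00    8.25",
            "  3: SEQC   12.00    8.25  100.00")
  m <- parse_pim(text)
  expect_identical(rownames(m), c("SEQA", "SEQB", "SEQC"))
  expect_identical(m["SEQA", "SEQB"], 62.50)
  expect_identical(m["SEQC", "SEQB"], 8.25)
  expect_error(parse_pim("1: ONLYROW 100.00 50.00"), class = "semdisc_parse_error")
})

test_that("the remote similarity route defers to the service's matrix", {
  service <- function(seqs) {
    # loopback service: computes the matrix locally, then prints pim text
    m <- similarity_matrix(seqs)
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste0(i, ": ", rownames(m)[i], " ",
             paste(formatC(m[i, ], format = "f", digits = 2), collapse = " "))
    }, "")
    paste(lines, collapse = "\n")
  }
  seqs <- c(A1 = "ACDEFGHIKL", A2 = "ACDEFGHIKW", A3 = "WYWYWYWYWY")
  m <- similarity_matrix_remote(seqs, service)
  expect_identical(m["A1", "A2"], 90)
  expect_identical(m["A1", "A3"], 0)
  broken <- function(seqs) stop("service unavailable")
  expect_error(similarity_matrix_remote(seqs, broken), class = "semdisc_lookup_error")
})
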