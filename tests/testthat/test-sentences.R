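test_that("tokenize splits on sentence boundaries but guards abbreviations", {
  expect_equal(tokenize("First sentence. Second |B1|."),
               c("First sentence.", "Second |B1|."))
  expect_equal(tokenize("See Fig. 2 for details."),
               "See Fig. 2 for details.")
  expect_equal(tokenize("Results of Smith et al. were confirmed."),
               "Results of Smith et al. were confirmed.")
  ## initials and decimals do not split
  expect_equal(tokenize("Work by J. Smith showed p < 0.05 overall."),
               "Work by J. Smith showed p < 0.05 overall.")
  ## question/exclamation boundaries
  expect_equal(tokenize("Is it true? It is. Good."),
               c("Is it true?", "It is.", "Good."))
  expect_equal(tokenize(""), character(0))
})

test_that("tokenize round-trips: joined output equals input", {
  texts <- c(
    "One sentence only.",
    "Alpha beta. Gamma delta |B2|. Epsilon zeta.",
    "A trial (n = 40). Results were clear [|B1|,|B2|].")
  for (tx in texts) {
    expect_equal(paste(tokenize(tx), collapse = " "), tx)
  }
})

test_that("compute_progression is a ceiling centile", {
  expect_equal(compute_progression(1, 1), 100L)
  expect_equal(compute_progression(1, 200), 1L)
  expect_equal(compute_progression(50, 200), 25L)
  ## brute-force property sweep: range, endpoints, monotonicity
  for (n in c(1:20, 150, 300)) {
    p <- compute_progression(seq_len(n), n)
    expect_true(all(p >= 1 & p <= 100))
    expect_equal(p[n], 100L)
    expect_true(all(diff(p) >= 0))
  }
  expect_error(compute_progression(5, 4))
})

test_that("build_records emits one row per citation and keeps ids shared", {
  art <- generate_article(dialect_config(n_refs = 10,
                                         implicit_style = "paired_xref",
                                         seed = 21))
  res <- process_article(art$xml)
  rec <- res$records
  ## row count = sum over sentences of max(1, citations)
  key <- paste(rec$location, rec$sentence_id, rec$text)
  per_sentence <- table(key)
  citing <- tapply(!is.na(rec$intxt_id), key, any)
  expect_true(all(per_sentence[!citing] == 1))
  ## rows of one sentence share all sentence-level fields
  for (k in names(per_sentence[per_sentence > 1])) {
    sub <- rec[key == k]
    expect_equal(length(unique(sub$sentence_id)), 1L)
    expect_equal(length(unique(sub$IMRaD)), 1L)
    expect_equal(length(unique(sub$progression)), 1L)
  }
  ## sentence_id <= total_sentences everywhere
  expect_true(all(rec$sentence_id <= rec$total_sentences))
  ## abstract rows are NoIMRaD
  expect_true(all(rec$IMRaD[rec$location == "abstract"] == "NoIMRaD"))
})

test_that("maintext progression mode spans body/table/figure jointly", {
  art <- generate_article(dialect_config(n_refs = 8, seed = 4))
  rec <- process_article(art$xml, progression_mode = "maintext")$records
  main <- rec$location %in% c("body", "table", "fig")
  dedup <- rec[!duplicated(paste(rec$location, rec$sentence_id, rec$text))]
  mm <- dedup[dedup$location %in% c("body", "table", "fig")]
  expect_true(all(diff(mm$progression) >= 0))
  expect_equal(mm$progression[nrow(mm)], 100L)
  ## abstract still per-component
  ab <- dedup[dedup$location == "abstract"]
  expect_equal(ab$progression[nrow(ab)], 100L)
})

test_that("write_tsv/read_tsv_records round-trip and sanitize", {
  art <- generate_article(dialect_config(n_refs = 6, seed = 2))
  rec <- process_article(art$xml)$records
  f <- tempfile(fileext = ".tsv")
  write_tsv(rec, f)
  back <- read_tsv_records(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  ## header-only file for zero records
  f2 <- tempfile(fileext = ".tsv")
  write_tsv(empty_records(), f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_tsv_records(f2)), 0L)
  ## tabs and newlines in text are flattened to spaces
  bad <- data.table::copy(rec[1])
  bad$text <- "has\ttab and\nnewline"
  f3 <- tempfile(fileext = ".tsv")
  write_tsv(bad, f3)
  expect_equal(read_tsv_records(f3)$text, "has tab and newline")
  ## 14-column mode drops text
  f4 <- tempfile(fileext = ".tsv")
  write_tsv(rec, f4, include_text = FALSE)
  expect_equal(
    strsplit(readLines(f4, n = 1), "\t")[[1]],
    c("pmcid", "pmid", "location", "IMRaD", "sentence_id",
      "total_sentences", "intxt_id", "intxt_pmid", "intxt_pmid_source",
      "intxt_mark", "best_id", "best_source", "best_id_diff", "progression"))
})
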