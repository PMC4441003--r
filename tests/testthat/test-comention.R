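# Co-mention extraction, bag-of-words, feature assembly and serialization.

mention_row <- function(doc, sent, kind, id, start = 0L, end = 1L) {
  tibble::tibble(doc_id = doc, sentence_index = as.integer(sent),
                 start = as.integer(start), end = as.integer(end),
                 surface = "x", kind = kind, concept_id = id,
                 provenance = "name")
}

test_that("sentence and non-sentence events follow the span definitions", {
  # no GO mentions at all -> empty
  m <- mention_row("d1", 0, "protein", "P1")
  expect_equal(nrow(extract_comentions(m)), 0)

  # protein in sentences {0, 2}, GO term in {0, 1}:
  # 1 sentence event (sentence 0); non-sentence pairs (0,1), (2,0), (2,1)
  m <- dplyr::bind_rows(
    mention_row("d1", 0, "protein", "P1"),
    mention_row("d1", 2, "protein", "P1"),
    mention_row("d1", 0, "go_term", "GO:0000001"),
    mention_row("d1", 1, "go_term", "GO:0000001")
  )
  cm <- extract_comentions(m)
  expect_equal(sum(cm$span == "sentence"), 1)
  expect_equal(cm$protein_sentence[cm$span == "sentence"], 0L)
  expect_equal(sum(cm$span == "non_sentence"), 3)

  # presence-based: repeated mentions in one sentence count once
  m2 <- dplyr::bind_rows(
    mention_row("d1", 0, "protein", "P1", 0, 2),
    mention_row("d1", 0, "protein", "P1", 10, 12),
    mention_row("d1", 0, "go_term", "GO:0000001", 4, 6),
    mention_row("d1", 0, "go_term", "GO:0000001", 14, 16)
  )
  cm2 <- extract_comentions(m2)
  expect_equal(nrow(cm2), 1)
  expect_equal(cm2$span, "sentence")
  # the mention-pair flag restores multiplicity
  cm2p <- extract_comentions(m2, mention_pair = TRUE)
  expect_equal(sum(cm2p$span == "sentence"), 4)

  # ambiguous protein mention contributes once per candidate accession
  m3 <- dplyr::bind_rows(
    mention_row("d1", 0, "protein", "P1"),
    mention_row("d1", 0, "protein", "P2"),
    mention_row("d1", 0, "go_term", "GO:0000001")
  )
  expect_setequal(extract_comentions(m3)$protein, c("P1", "P2"))
})

test_that("extraction equals brute-force sentence-pair enumeration", {
  set.seed(99)
  for (i in 1:100) {
    n_sent <- sample(1:5, 1)
    rows <- list()
    for (k in seq_len(sample(2:8, 1))) {
      kind <- sample(c("protein", "go_term"), 1)
      id <- if (kind == "protein") sample(c("P1", "P2", "P3"), 1) else
        sample(sprintf("GO:%07d", 1:3), 1)
      rows[[k]] <- mention_row("d1", sample(n_sent, 1) - 1L, kind, id)
    }
    m <- dplyr::bind_rows(rows)
    got <- canonical_comentions(extract_comentions(m))
    want <- oracle_comentions(m)
    expect_equal(got, want)
    # events disjoint and exhaustive: spans partition the event set
    expect_equal(nrow(got),
                 sum(got$span == "sentence") + sum(got$span == "non_sentence"))
  }
})

test_that("bag-of-words lowercases, drops stopwords, accumulates", {
  sen <- tibble::tibble(
    doc_id = c("d1", "d1", "d2"), unit_kind = "abstract",
    sentence_index = c(0L, 1L, 0L),
    start = c(0L, 24L, 0L), end = c(23L, 40L, 18L),
    sentence = c("P53 inhibits the growth", "No mention here",
                 "p53 alters Growth")
  )
  pm <- dplyr::bind_rows(
    mention_row("d1", 0, "protein", "P04637", 0, 3),
    mention_row("d2", 0, "protein", "P04637", 0, 3)
  )
  bow <- extract_bow(sen, pm, stopwords = "the")
  expect_setequal(bow$word, c("p53", "inhibits", "growth", "alters"))
  # "Growth" and "growth" in two mention sentences pool into one key
  expect_equal(bow$count[bow$word == "growth"], 2)
  expect_equal(bow$count[bow$word == "p53"], 2)
  # sentence without protein mention contributes nothing
  expect_false(any(grepl("mention|here|no", bow$word)))

  # masking the protein's own tokens
  bow2 <- extract_bow(sen, pm, stopwords = "the",
                      include_protein_tokens = FALSE)
  expect_false("p53" %in% bow2$word)
  expect_equal(bow2$count[bow2$word == "growth"], 2)
})

test_that("feature assembly modes aggregate and conserve counts", {
  cm <- tibble::tibble(
    protein = "P1", go_id = "GO:0000001", doc_id = "d1",
    span = c(rep("sentence", 2), rep("non_sentence", 3)),
    protein_sentence = 0L, go_sentence = c(0L, 0L, 1L, 1L, 2L)
  )
  sep <- assemble_features(cm, mode = "separate")
  expect_setequal(sep$feature, c("co_GO:0000001", "nco_GO:0000001"))
  expect_equal(sep$count[sep$feature == "co_GO:0000001"], 2)
  expect_equal(sep$count[sep$feature == "nco_GO:0000001"], 3)

  comb <- assemble_features(cm, mode = "combined")
  expect_equal(comb$feature, "co_GO:0000001")
  expect_equal(comb$count, 5)

  expect_equal(assemble_features(cm, mode = "sentence_only")$count, 2)
  expect_equal(assemble_features(cm, mode = "nonsentence_only")$count, 3)
  expect_error(assemble_features(cm, mode = "frequency"))
  expect_error(assemble_features(NULL, mode = "separate"), "co-mentions")

  bow <- tibble::tibble(protein = "P1", word = "growth", count = 4L)
  all3 <- assemble_features(cm, bow, mode = "comentions_plus_bow")
  expect_setequal(all3$feature,
                  c("co_GO:0000001", "nco_GO:0000001", "w_growth"))

  # conservation on random synthetic corpora
  for (seed in 1:3) {
    res <- run_baseline(synth_config(n_proteins = 15, n_terms = 12,
                                     seed = seed))
    s <- assemble_features(res$comentions, mode = "separate")
    cb <- assemble_features(res$comentions, mode = "combined")
    expect_equal(sum(cb$count), sum(s$count))
  }
})

test_that("feature files use the sparse key=value record format", {
  ft <- structure(
    tibble::tibble(
      protein = c("Q9ZPY7", "Q9ZPY7"),
      feature = c("co_GO:0003675", "co_GO:0005623"),
      count = c(6L, 2L)),
    class = c("feature_table", class(tibble::tibble())))
  p <- withr::local_tempfile(fileext = ".txt")
  write_features(ft, p)
  expect_equal(readLines(p), "Q9ZPY7, co_GO:0003675=6, co_GO:0005623=2")
  expect_equal(as.data.frame(read_features(p)), as.data.frame(ft))

  # empty table -> empty file
  write_features(ft[0, ], p)
  expect_equal(length(readLines(p)), 0)
  expect_equal(nrow(read_features(p)), 0)

  # random table round-trip
  set.seed(7)
  rnd <- structure(
    dplyr::arrange(tibble::tibble(
      protein = sample(sprintf("SYNP%04d", 1:6), 40, replace = TRUE),
      feature = sample(c(sprintf("co_GO:%07d", 1:5),
                         sprintf("w_word%d", 1:5)), 40, replace = TRUE),
      count = sample.int(50, 40, replace = TRUE)
    ) |> dplyr::distinct(protein, feature, .keep_all = TRUE),
    protein, feature),
    class = c("feature_table", class(tibble::tibble())))
  write_features(rnd, p)
  expect_equal(as.data.frame(read_features(p)), as.data.frame(rnd))

  writeLines("P1, co_GO:0000001=notanumber", p)
  expect_error(read_features(p), "malformed")
})

test_that("co-mention summary statistics match hand counts", {
  empty <- extract_comentions(mention_row("d", 0, "protein", "P1"))
  st0 <- comention_stats(empty)
  expect_true(all(st0$n_comentions == 0))

  cm <- tibble::tibble(
    protein = c("P1", "P1", "P2", "P2", "P2"),
    go_id = c("GO:0000001", "GO:0000001", "GO:0000001",
              "GO:0000002", "GO:0000002"),
    doc_id = paste0("d", 1:5),
    span = c("sentence", "non_sentence", "sentence", "sentence",
             "non_sentence"),
    protein_sentence = 0L, go_sentence = c(0L, 1L, 0L, 0L, 2L)
  )
  st <- comention_stats(cm)
  s <- st[st$span == "sentence", ]
  expect_equal(unlist(s[, -1]), c(n_proteins = 2, n_go_terms = 2,
                                  n_pairs = 3, n_comentions = 3))
  comb <- st[st$span == "combined", ]
  expect_equal(comb$n_pairs, 3)       # union deduplicates (P1,g1), (P2,g2)
  expect_equal(comb$n_comentions, 5)  # totals always add

  stsum <- comention_stats(cm, combined = "sum")
  expect_equal(stsum$n_pairs[stsum$span == "combined"], 5)

  # union combined uniques never exceed the per-span sums
  expect_true(comb$n_pairs <= sum(st$n_pairs[st$span != "combined"]))
})
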