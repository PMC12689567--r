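test_that("tokenizer protects lexicon terms and drops digit tokens wholesale", {
  toks <- tokenize("big data improves big data quality", lexicon = "big data")
  expect_equal(toks, c("big data", "improves", "big data", "quality"))
  expect_equal(tokenize("a1 b2!! c"), "c")
  expect_equal(tokenize(""), character(0))
  expect_error(tokenize("x", tokenizer = "nope"), class = "pmcindex_input_error")
})

test_that("custom tokenizer plugins can be registered and used", {
  register_tokenizer("chars", function(text, lexicon) {
    strsplit(text, "")[[1]]
  })
  expect_equal(tokenize("ab", tokenizer = "chars"), c("a", "b"))
})

test_that("stop-word filtering removes the union of lists, case-folded, idempotently", {
  toks <- c("The", "quality", "of", "care")
  expect_equal(filter_stopwords(toks, c("the", "of")), c("quality", "care"))
  expect_equal(filter_stopwords(toks, character(0)), toks)
  expect_equal(filter_stopwords(toks, c("the", "the", "of")),
               filter_stopwords(toks, c("the", "of")))
  expect_equal(filter_stopwords(toks, "the", fold_case = FALSE),
               c("The", "quality", "of", "care"))
  f <- withr::local_tempfile(lines = c("of", "care"))
  expect_equal(filter_stopwords(toks, list("the", f)), "quality")
})

test_that("term frequencies rank descending with lexicographic ties", {
  tab <- term_frequencies(c("c", "c", "c", "b", "b", "a"))
  expect_equal(tab$term, c("c", "b", "a"))
  expect_equal(tab$frequency, c(3L, 2L, 1L))
  expect_equal(tab$rank, 1:3)
  tie <- term_frequencies(c(rep("zeta", 5), rep("alpha", 5)))
  expect_equal(tie$term, c("alpha", "zeta"))
  empty <- term_frequencies(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("document and window co-occurrence counts are as defined", {
  toks <- tibble::tibble(doc_id = "d1", token = c("a", "b"))
  net <- cooccurrence_network(toks)
  expect_equal(net$edges$weight, 1L)
  expect_equal(c(net$edges$term_a, net$edges$term_b), c("a", "b"))
  # min_weight above the max prunes edges but keeps nodes
  net2 <- cooccurrence_network(toks, min_weight = 5)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(nrow(net2$nodes), 2)
  # sliding windows: a and c never share a window of length 2
  toks3 <- tibble::tibble(doc_id = "d1", token = c("a", "b", "c"))
  net3 <- cooccurrence_network(toks3, window = 2)
  expect_false(any(net3$edges$term_a == "a" & net3$edges$term_b == "c"))
})

test_that("planted corpora are recovered exactly end to end", {
  vocab <- tibble::tibble(term = c("alpha", "beta", "gamma", "noise"),
                          frequency = c(8L, 6L, 5L, 3L))
  pairs <- tibble::tibble(term_a = c("alpha", "beta"),
                          term_b = c("beta", "gamma"),
                          count = c(3L, 2L))
  gc <- generate_corpus(vocab, pairs, n_docs = 12, seed = 9)
  toks <- tokenize(gc$documents)
  tf <- term_frequencies(toks)
  expect_equal(dplyr::arrange(tibble::as_tibble(tf[c("term", "frequency")]), term),
               dplyr::arrange(gc$ledger$term_frequencies, term))
  # frequency conservation: table total equals token count
  expect_equal(sum(tf$frequency), nrow(toks))
  net <- cooccurrence_network(toks)
  for (i in seq_len(nrow(pairs))) {
    key <- sort(c(pairs$term_a[i], pairs$term_b[i]))
    w <- net$edges$weight[net$edges$term_a == key[1] & net$edges$term_b == key[2]]
    expect_equal(w, pairs$count[i])
  }
  # no unplanned co-occurrences
  expect_equal(nrow(net$edges), nrow(pairs))
  # determinism: same seed, same corpus
  gc2 <- generate_corpus(vocab, pairs, n_docs = 12, seed = 9)
  expect_identical(gc$documents, gc2$documents)
})

test_that("word-cloud export preserves weights", {
  tab <- term_frequencies(c("x", "x", "y"))
  f <- withr::local_tempfile(fileext = ".csv")
  export_wordcloud_data(tab, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(sum(back$weight), 3)
})
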