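test_that("pmc_index sums exact thirds and enforces bounds", {
  expect_equal(pmc_index(c(2, 3, 3, 2, 3, 2, 3, 3, 3), rep(3, 9)), 8)
  expect_equal(round_half_up(pmc_index(c(3, 3, 3, 1, 3, 3, 2, 2, 2), rep(3, 9)), 2), 7.33)
  expect_equal(pmc_index(rep(3, 9), rep(3, 9)), 9)
  expect_error(pmc_index(c(4, rep(3, 8)), rep(3, 9)), class = "pmcindex_input_error")
  expect_error(pmc_index(1:3, rep(3, 2)), class = "pmcindex_input_error")
})

test_that("dimension scores are exact numerator/denominator means", {
  m <- constant_matrix(n = 1, value = 0)
  row <- tibble::as_tibble(m)
  row[c("X1-1", "X1-2")] <- 1L
  ds <- dimension_scores(as_coding_matrix(row))
  expect_equal(ds$numerator[ds$dimension == "X1"], 2L)
  expect_equal(ds$score[ds$dimension == "X1"], 2 / 3)
  expect_true(all(ds$score[ds$dimension != "X1"] == 0))
})

test_that("a single all-zero policy grades Poor at rank 1", {
  ev <- evaluate_corpus(constant_matrix(n = 1, value = 0))
  sc <- tidy(ev)
  expect_equal(sc$pmc, 0)
  expect_equal(as.character(sc$grade), "Poor")
  expect_equal(sc$rank, 1L)
})

test_that("flipping any single 0 to 1 raises that policy's index by exactly 1/3", {
  fx <- mqimp_fixture()
  base_m <- reconstruct_matrix(fx$scores, fx$counts)
  base <- tidy(evaluate_corpus(base_m))
  tab <- tibble::as_tibble(base_m)
  zeros <- which(as.matrix(tab[, -1]) == 0, arr.ind = TRUE)
  set.seed(42)
  for (k in sample(nrow(zeros), 12)) {
    flipped <- tab
    flipped[[zeros[k, "col"] + 1]][zeros[k, "row"]] <- 1L
    after <- tidy(evaluate_corpus(as_coding_matrix(flipped)))
    pid <- tab$policy_id[zeros[k, "row"]]
    delta <- after$pmc[after$policy_id == pid] - base$pmc[base$policy_id == pid]
    expect_equal(delta, 1 / 3, tolerance = 1e-12)
  }
})

test_that("matrix-level and first-level evaluation agree whenever marginals match", {
  fx <- mqimp_fixture()
  ev_first <- evaluate_from_first_level(fx$scores)
  ev_matrix <- evaluate_corpus(reconstruct_matrix(fx$scores, fx$counts))
  expect_equal(tidy(ev_first), tidy(ev_matrix))
  expect_equal(glance(ev_first), glance(ev_matrix))
  expect_equal(ev_first$dimension_averages, ev_matrix$dimension_averages)
})

test_that("ranks are a permutation with non-increasing index and stable ties", {
  fx <- mqimp_fixture()
  sc <- tidy(evaluate_from_first_level(fx$scores))
  expect_equal(sort(sc$rank), seq_len(nrow(sc)))
  expect_true(all(diff(sc$pmc) <= 1e-12))
  # the two 8.00 policies keep their input order
  expect_equal(sc$policy_id[1:2], c("P11", "P6"))
})

test_that("average index equals total ones over 3n (conservation)", {
  fx <- mqimp_fixture()
  ev <- evaluate_from_first_level(fx$scores)
  expect_equal(ev$total_ones, 415)
  expect_equal(ev$average_pmc, 415 / 66, tolerance = 1e-14)
  per_policy <- tidy(ev)
  expect_equal(sum(per_policy$pmc) * 3, 415, tolerance = 1e-9)
})

test_that("non-third first-level scores are rejected", {
  fx <- mqimp_fixture()
  bad <- fx$scores
  bad$X1[1] <- 0.5
  expect_error(evaluate_from_first_level(bad), class = "pmcindex_input_error",
               regexp = "X1")
})

test_that("evaluation works on non-default schema shapes", {
  schema <- mini_schema(2, 2)
  m <- tibble::tibble(policy_id = "A", `D1-1` = 1, `D1-2` = 1, `D2-1` = 1, `D2-2` = 0)
  scale <- default_grade_scale()
  ev <- evaluate_corpus(as_coding_matrix(m, schema), schema, scale)
  expect_equal(tidy(ev)$pmc, 1.5)
})
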