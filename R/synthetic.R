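#' Generate a synthetic binary coding matrix
#'
#' Emulates a policy-corpus coding exercise with known ground truth. Two
#' modes: `"stochastic"` draws each cell independently as Bernoulli(p_j) for
#' its indicator's coverage probability; `"quota"` places exactly
#' round(p_j x n) ones per indicator column, at seeded random policy
#' positions, so coverage is recovered exactly.
#'
#' @param n_policies number of synthetic policies.
#' @param coverage per-indicator coverage probabilities in `[0, 1]`: a vector
#'   of length `nrow(schema)` (optionally named by indicator code).
#' @param seed integer seed governing all randomness.
#' @param mode `"stochastic"` or `"quota"`.
#' @param schema a `pmc_schema`.
#' @return a `pmc_coding` matrix with policy ids `S1..Sn`.
#' @export
#' @examples
#' m <- generate_coding_matrix(22, rep(0.5, 27), seed = 7, mode = "quota")
#' coverage_rates(m)
generate_coding_matrix <- function(n_policies, coverage, seed = 1,
                                   mode = c("stochastic", "quota"),
                                   schema = default_schema()) {
  mode <- match.arg(mode)
  if (length(coverage) != nrow(schema)) {
    abort(sprintf("coverage must have one probability per schema secondary (%d)",
                  nrow(schema)), class = "pmcindex_input_error")
  }
  if (any(coverage < 0 | coverage > 1)) {
    abort("coverage probabilities must lie in [0, 1]", class = "pmcindex_input_error")
  }
  if (!is.null(names(coverage))) coverage <- coverage[schema$code]
  out <- tibble(policy_id = paste0("S", seq_len(n_policies)))
  cells <- with_seed_local(seed, {
    lapply(seq_along(coverage), function(j) {
      if (mode == "stochastic") {
        rbinom(n_policies, 1, coverage[j])
      } else {
        k <- round(coverage[j] * n_policies)
        v <- integer(n_policies)
        v[sample.int(n_policies, k)] <- 1L
        v
      }
    })
  })
  for (j in seq_along(cells)) out[[schema$code[j]]] <- as.integer(cells[[j]])
  as_coding_matrix(out, schema)
}

#' Bundled evaluation data: 22 Chinese medical-quality policies
#'
#' The packaged transcription of the evaluation of 22 Chinese national
#' medical-quality intelligent-management policies (2016-2025): the per-policy
#' first-level score table (exact thirds, ranked order) and the per-secondary
#' ones-counts at n = 22. The X8-1/X8-2 counts are a synthetic split (flagged
#' in the `synthetic` column): only their sum (38) is determined by the score
#' table, the published indicator-level summary for X8 being internally
#' inconsistent for binary data; X8-3 = 1 is documented coverage (4.55%).
#'
#' Self-checks run on every load: per-dimension ones totals from the counts
#' equal 3 x the score-column sums, the grand total of ones is 415, and
#' 415/66 displays as the published average 6.29.
#'
#' @return list with `scores` (22 x 10 tibble), `counts` (27-row tibble:
#'   `code`, `count`, `n`, `synthetic`), `schema`, `scale`, and `metadata`.
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' sum(fx$counts$count) # 415
mqimp_fixture <- function() {
  schema <- default_schema()
  scale <- default_grade_scale()
  scores <- readr::read_csv(
    system.file("extdata", "mqimp_scores.csv", package = "pmcindex"),
    show_col_types = FALSE
  )
  counts <- readr::read_csv(
    system.file("extdata", "mqimp_counts.csv", package = "pmcindex"),
    show_col_types = FALSE
  )
  # packaging self-checks
  dims <- schema_dimensions(schema)
  for (i in seq_len(nrow(dims))) {
    d <- dims$dimension[i]
    col_total <- sum(counts$count[sub("-.*$", "", counts$code) == d])
    row_total <- sum(thirds_to_numerator(scores[[d]], dims$n_secondary[i]))
    if (col_total != row_total) {
      abort(sprintf("fixture checksum failure in dimension %s (%d vs %d)",
                    d, col_total, row_total), class = "pmcindex_packaging_error")
    }
  }
  total <- sum(counts$count)
  if (total != 415 || round_half_up(total / 66, 2) != 6.29) {
    abort("fixture checksum failure: grand total of ones", class = "pmcindex_packaging_error")
  }
  list(
    scores = scores,
    counts = counts,
    schema = schema,
    scale = scale,
    metadata = list(
      n_policies = nrow(scores),
      total_ones = total,
      note = paste("X8-1/X8-2 split is synthetic; only the sum 38 is",
                   "determined by the score table")
    )
  )
}

#' Generate a synthetic token corpus with known ground truth
#'
#' Builds documents whose post-tokenization term frequencies and
#' document-level co-occurrences equal a planted ledger exactly, so the
#' text-mining pipeline can be tested end to end without any real corpus.
#' Construction: each planted co-occurring pair gets dedicated documents
#' containing exactly that pair; each term's remaining frequency mass goes
#' into documents of its own, so no unplanned pair co-occurrence can arise.
#' The seed only shuffles document order and within-document token order
#' (both immaterial to frequencies and document co-occurrence).
#'
#' @param vocabulary tibble with `term` and `frequency` (total occurrences).
#' @param pairs tibble with `term_a`, `term_b`, `count` (documents in which
#'   the pair must co-occur), or NULL for none.
#' @param n_docs number of documents; must be at least sum(pairs$count) +
#'   number of terms with leftover mass.
#' @param seed integer seed.
#' @return list with `documents` (tibble `doc_id`, `text`) and `ledger`
#'   (list: `term_frequencies`, `cooccurrences`).
#' @export
#' @examples
#' gc <- generate_corpus(tibble::tibble(term = c("a", "b"), frequency = c(4, 3)),
#'                       pairs = tibble::tibble(term_a = "a", term_b = "b", count = 2),
#'                       n_docs = 5, seed = 1)
#' term_frequencies(tokenize(gc$documents))
generate_corpus <- function(vocabulary, pairs = NULL, n_docs, seed = 1) {
  vocabulary <- as_tibble(vocabulary)
  if (any(vocabulary$frequency < 0)) {
    abort("frequencies must be non-negative", class = "pmcindex_input_error")
  }
  pairs <- if (is.null(pairs)) {
    tibble(term_a = character(), term_b = character(), count = integer())
  } else {
    as_tibble(pairs)
  }
  remaining <- stats::setNames(vocabulary$frequency, vocabulary$term)
  doc_tokens <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$term_a[i]; b <- pairs$term_b[i]
    if (!(a %in% names(remaining)) || !(b %in% names(remaining))) {
      abort(sprintf("pair (%s, %s) references term(s) missing from vocabulary", a, b),
            class = "pmcindex_input_error")
    }
    k <- pairs$count[i]
    if (remaining[a] < k || remaining[b] < k) {
      abort(sprintf("pair (%s, %s) needs %d occurrences of each term; not enough frequency mass",
                    a, b, k), class = "pmcindex_input_error")
    }
    for (j in seq_len(k)) doc_tokens[[length(doc_tokens) + 1]] <- c(a, b)
    remaining[a] <- remaining[a] - k
    remaining[b] <- remaining[b] - k
  }
  for (t in names(remaining)) {
    if (remaining[t] > 0) {
      doc_tokens[[length(doc_tokens) + 1]] <- rep(t, remaining[t])
    }
  }
  if (length(doc_tokens) > n_docs) {
    abort(sprintf("config unrealizable: needs at least %d documents, n_docs = %d",
                  length(doc_tokens), n_docs), class = "pmcindex_input_error")
  }
  while (length(doc_tokens) < n_docs) doc_tokens[[length(doc_tokens) + 1]] <- character(0)
  doc_tokens <- with_seed_local(seed, {
    shuffled <- sample(doc_tokens)
    lapply(shuffled, function(x) if (length(x) > 1) sample(x) else x)
  })
  documents <- tibble(
    doc_id = sprintf("D%03d", seq_len(n_docs)),
    text = purrr::map_chr(doc_tokens, paste, collapse = " ")
  )
  ledger <- list(
    term_frequencies = arrange(vocabulary, desc(.data$frequency), .data$term),
    cooccurrences = pairs
  )
  list(documents = documents, ledger = ledger)
}
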