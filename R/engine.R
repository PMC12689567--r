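#' Dimension scores for a coding matrix
#'
#' A first-level dimension score is the unweighted mean of its binary
#' second-level indicators, held exactly as an integer numerator over the
#' number of secondaries T (here T = 3, so scores are exact thirds and display
#' as 0, 0.33, 0.67, 1.00). Display rounding never feeds back into
#' computation.
#'
#' @param matrix a `pmc_coding` coding matrix.
#' @param schema a `pmc_schema`.
#' @return tibble with `policy_id`, `dimension`, `numerator`, `denominator`,
#'   `score` (= numerator/denominator).
#' @export
dimension_scores <- function(matrix, schema = default_schema()) {
  dims <- schema_dimensions(schema)
  purrr::map_dfr(seq_len(nrow(dims)), function(i) {
    d <- dims$dimension[i]
    sec <- schema$code[schema$dimension == d]
    num <- rowSums(as_tibble(matrix)[, sec, drop = FALSE])
    tibble(
      policy_id = matrix$policy_id,
      dimension = d,
      numerator = as.integer(num),
      denominator = dims$n_secondary[i],
      score = num / dims$n_secondary[i]
    )
  })
}

#' PMC index from dimension scores
#'
#' The index of a policy is the sum of its first-level dimension scores, so it
#' ranges from 0 to the number of dimensions (0-9 for the bundled schema). The
#' sum is carried out in exact integer arithmetic over the least common
#' denominator, so boundary values (e.g. 24/3 = 8.00) grade correctly.
#'
#' @param numerators integer vector, one satisfied-secondary count per
#'   dimension.
#' @param denominators integer vector of secondaries per dimension (T).
#' @return the exact index value as a double (single exact division).
#' @export
#' @examples
#' pmc_index(c(2, 3, 3, 2, 3, 2, 3, 3, 3), rep(3, 9)) # 8
pmc_index <- function(numerators, denominators) {
  if (length(numerators) != length(denominators)) {
    abort("one numerator per dimension required", class = "pmcindex_input_error")
  }
  if (any(numerators < 0) || any(numerators > denominators)) {
    abort("numerators must lie in [0, T] per dimension", class = "pmcindex_input_error")
  }
  l <- lcm_all(denominators)
  sum(numerators * (l / denominators)) / l
}

# shared constructor: numer = policy x dimension integer matrix
new_pmc_evaluation <- function(policy_ids, numer, denom, scale, schema) {
  l <- lcm_all(denom)
  pmc_units <- as.vector(numer %*% (l / denom)) # integer totals over denominator l
  pmc <- pmc_units / l
  ord <- order(-pmc_units, seq_along(pmc_units)) # stable: ties keep input order
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  grade <- classify_grade(pmc, scale)

  score_cols <- as_tibble(sweep(numer, 2, denom, `/`))
  scorecards <- dplyr::bind_cols(tibble(policy_id = policy_ids), score_cols) |>
    mutate(
      pmc = pmc,
      pmc_display = round_half_up(pmc, 2),
      grade = grade,
      rank = rank
    ) |>
    arrange(rank)

  avg_units <- colSums(numer) # total ones per dimension
  n <- length(policy_ids)
  dimension_averages <- tibble(
    dimension = colnames(numer),
    total_ones = as.integer(unname(avg_units)),
    average = unname(avg_units / (denom * n)),
    display = unname(round_half_up(avg_units / (denom * n), 2))
  )
  average_pmc <- sum(pmc_units) / (l * n)
  hist <- scorecards |>
    count(grade, .drop = FALSE) |>
    rename(n_policies = n)

  structure(
    list(
      scorecards = scorecards,
      dimension_averages = dimension_averages,
      average_pmc = average_pmc,
      average_pmc_display = round_half_up(average_pmc, 2),
      average_grade = classify_grade(average_pmc, scale),
      grade_histogram = hist,
      n_policies = n,
      total_ones = sum(colSums(numer)),
      scale = scale,
      schema = schema
    ),
    class = "pmc_evaluation"
  )
}

#' Evaluate a policy corpus from a binary coding matrix
#'
#' Scores every policy (dimension means, PMC index, grade, rank) and the
#' corpus (dimension averages, average index, grade histogram). Ranks are by
#' index descending with ties kept in input order.
#'
#' @param matrix a `pmc_coding` coding matrix.
#' @param schema a `pmc_schema`.
#' @param scale a `pmc_grade_scale`.
#' @return a `pmc_evaluation` object; see [tidy.pmc_evaluation()] and
#'   [glance.pmc_evaluation()].
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' ev <- evaluate_from_first_level(fx$scores)
#' glance(ev)
evaluate_corpus <- function(matrix, schema = default_schema(),
                            scale = default_grade_scale()) {
  matrix <- as_coding_matrix(matrix, schema)
  dims <- schema_dimensions(schema)
  numer <- do.call(cbind, lapply(dims$dimension, function(d) {
    sec <- schema$code[schema$dimension == d]
    as.integer(rowSums(as_tibble(matrix)[, sec, drop = FALSE]))
  }))
  colnames(numer) <- dims$dimension
  new_pmc_evaluation(matrix$policy_id, numer, dims$n_secondary, scale, schema)
}

#' @rdname evaluate_corpus
#' @param scores data frame of pre-aggregated first-level scores: `policy_id`
#'   plus one column per dimension, values exact thirds displayed at two
#'   decimals (0, 0.33, 0.67, 1). This is the direct path when only
#'   first-level scores are available; it agrees exactly with
#'   [evaluate_corpus()] on any coding matrix with matching dimension sums.
#' @export
evaluate_from_first_level <- function(scores, schema = default_schema(),
                                      scale = default_grade_scale()) {
  scores <- as_tibble(scores)
  dims <- schema_dimensions(schema)
  missing_cols <- setdiff(dims$dimension, names(scores))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing dimension column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "pmcindex_input_error")
  }
  numer <- do.call(cbind, lapply(seq_len(nrow(dims)), function(i) {
    thirds_to_numerator(scores[[dims$dimension[i]]], denom = dims$n_secondary[i],
                        what = sprintf("dimension %s", dims$dimension[i]))
  }))
  colnames(numer) <- dims$dimension
  new_pmc_evaluation(scores$policy_id, numer, dims$n_secondary, scale, schema)
}

#' @export
print.pmc_evaluation <- function(x, ...) {
  cat(sprintf("PMC evaluation of %d policies\n", x$n_policies))
  cat(sprintf("Average PMC index: %.2f (%s)\n",
              x$average_pmc_display, as.character(x$average_grade)))
  cat("Grade histogram:\n")
  print(as.data.frame(x$grade_histogram), row.names = FALSE)
  cat("Top of ranking:\n")
  print(head(as.data.frame(x$scorecards[, c("policy_id", "pmc_display", "grade", "rank")]), 5),
        row.names = FALSE)
  invisible(x)
}

#' Tidy a PMC evaluation into per-policy scorecards
#'
#' @param x a `pmc_evaluation`.
#' @param ... unused.
#' @return tibble of scorecards, ranked: `policy_id`, one column per dimension
#'   (exact scores), `pmc`, `pmc_display`, `grade`, `rank`.
#' @method tidy pmc_evaluation
#' @export
tidy.pmc_evaluation <- function(x, ...) x$scorecards

#' One-row summary of a PMC evaluation
#'
#' @inheritParams tidy.pmc_evaluation
#' @return one-row tibble: `n_policies`, `average_pmc`, `average_pmc_display`,
#'   `average_grade`, `total_ones`.
#' @method glance pmc_evaluation
#' @export
glance.pmc_evaluation <- function(x, ...) {
  tibble(
    n_policies = x$n_policies,
    average_pmc = x$average_pmc,
    average_pmc_display = x$average_pmc_display,
    average_grade = as.character(x$average_grade),
    total_ones = x$total_ones
  )
}

#' Radar plot of corpus dimension averages
#'
#' @param object a `pmc_evaluation`.
#' @param threshold dimensions below this average are highlighted.
#' @param ... unused.
#' @return a ggplot object (polar bar layout, one spoke per dimension).
#' @method autoplot pmc_evaluation
#' @export
autoplot.pmc_evaluation <- function(object, threshold = 0.6, ...) {
  dat <- radar_data(object, threshold = threshold)
  ggplot(dat, aes(x = .data$dimension, y = .data$average, fill = .data$flagged)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick")) +
    ggplot2::labs(y = "average dimension score", x = NULL,
                  fill = sprintf("below %.2f", threshold))
}
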