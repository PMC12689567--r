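#' Within-dimension contingency table
#'
#' For one first-level dimension, arranges its second-level indicators as a
#' 3 x 2 contingency table of (ones, zeros) counts over the corpus: each row
#' is one indicator, rows sum to the number of policies n. The Pearson
#' chi-square test of homogeneity on this table asks whether the indicators
#' inside a dimension are covered at systematically different rates.
#'
#' @param counts coverage table (`code`, `count`, `n`).
#' @param dimension first-level dimension code (prefix of the secondary
#'   codes, e.g. `"X6"`).
#' @return integer matrix with indicator codes as row names and columns
#'   `ones`, `zeros`.
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' tab <- within_dimension_table(fx$counts, "X1")
#' pearson_chisq(tab)
within_dimension_table <- function(counts, dimension) {
  counts <- as_tibble(counts)
  rows <- filter(counts, sub("-.*$", "", .data$code) == dimension)
  if (nrow(rows) == 0) {
    abort(sprintf("no secondaries found for dimension %s", dimension),
          class = "pmcindex_input_error")
  }
  m <- cbind(ones = rows$count, zeros = rows$n - rows$count)
  rownames(m) <- rows$code
  storage.mode(m) <- "integer"
  if (any(m < 0)) abort("counts exceed n", class = "pmcindex_input_error")
  m
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic sum((O - E)^2 / E) with expected counts from the
#' row/column margins and no continuity correction; df = (rows-1)(cols-1).
#' Degenerate tables whose column margin is constant (all ones or all zeros)
#' have no variation to test; the statistic is then defined as 0 with p = 1
#' and a warning. Expected counts below 5 trigger a warning but do not block,
#' since small policy corpora routinely violate the rule of thumb.
#'
#' @param table integer matrix of observed counts (e.g. from
#'   [within_dimension_table()]).
#' @return a `pmc_chisq` list: `statistic`, `df`, `p_value`, `expected`,
#'   `degenerate`. Has [tidy()] and [glance()] methods.
#' @export
pearson_chisq <- function(table) {
  table <- as.matrix(table)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  if (any(colSums(table) == 0)) {
    warn("degenerate contingency table (a column margin is zero); statistic defined as 0")
    res <- list(statistic = 0, df = df, p_value = 1,
                expected = table * NA_real_, degenerate = TRUE)
    return(structure(res, class = "pmc_chisq"))
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn("expected count(s) below 5; chi-square approximation is rough")
  }
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), expected = ct$expected, degenerate = FALSE),
    class = "pmc_chisq"
  )
}

#' @export
print.pmc_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: %.4f on %d df, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate table)" else ""))
  invisible(x)
}

#' @method tidy pmc_chisq
#' @export
tidy.pmc_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         degenerate = x$degenerate)
}

#' @method glance pmc_chisq
#' @export
glance.pmc_chisq <- function(x, ...) tidy(x)

#' Chi-square consistency check for every dimension
#'
#' @param counts coverage table (`code`, `count`, `n`) covering the whole
#'   schema.
#' @param schema a `pmc_schema`.
#' @return tibble with one row per dimension: `dimension`, `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
dimension_chisq <- function(counts, schema = default_schema()) {
  dims <- schema_dimensions(schema)
  purrr::map_dfr(dims$dimension, function(d) {
    res <- pearson_chisq(within_dimension_table(counts, d))
    dplyr::bind_cols(tibble(dimension = d), tidy(res))
  })
}

#' Per-indicator mean and within-group standard deviation
#'
#' For a binary indicator with `count` ones among `n` policies: mean = p =
#' count/n, and the within SD is the n-1 sample standard deviation of the 0/1
#' column, sqrt(n p (1 - p) / (n - 1)).
#'
#' @param counts coverage table (`code`, `count`, `n`), n >= 2.
#' @return tibble with `code`, `mean`, `within_sd`.
#' @export
#' @examples
#' indicator_summary(tibble::tibble(code = "X1-1", count = 21, n = 22))
indicator_summary <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$n < 2)) {
    abort("within SD requires n >= 2", class = "pmcindex_input_error")
  }
  counts |>
    mutate(
      mean = .data$count / .data$n,
      within_sd = sqrt(.data$n * .data$mean * (1 - .data$mean) / (.data$n - 1))
    ) |>
    select("code", "mean", "within_sd")
}
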