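#' Validate a binary coding matrix
#'
#' A coding matrix records, per policy document and second-level indicator,
#' whether the policy text explicitly addresses the criterion (1) or not (0).
#' It is a tibble with a `policy_id` column followed by one 0/1 column per
#' schema secondary, in schema order.
#'
#' @param x a data frame with `policy_id` plus indicator columns.
#' @param schema a `pmc_schema`; defaults to the bundled 9 x 3 system.
#' @return the validated coding matrix as a `pmc_coding` tibble.
#' @export
as_coding_matrix <- function(x, schema = default_schema()) {
  x <- as_tibble(x)
  if (!"policy_id" %in% names(x)) {
    abort("coding matrix must have a 'policy_id' column", class = "pmcindex_input_error")
  }
  missing_cols <- setdiff(schema$code, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("coding matrix missing indicator column(s): %s",
                  paste(missing_cols, collapse = ", ")), class = "pmcindex_input_error")
  }
  extra <- setdiff(names(x), c("policy_id", schema$code))
  if (length(extra) > 0) {
    abort(sprintf("unknown indicator column(s): %s", paste(extra, collapse = ", ")),
          class = "pmcindex_input_error")
  }
  x <- select(x, "policy_id", dplyr::all_of(schema$code))
  if (anyDuplicated(x$policy_id)) {
    abort("policy_id values must be unique", class = "pmcindex_input_error")
  }
  for (code in schema$code) {
    v <- x[[code]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("non-binary cell at policy '%s', indicator '%s' (value: %s)",
                    x$policy_id[bad[1]], code, as.character(v[bad[1]])),
            class = "pmcindex_io_error")
    }
    x[[code]] <- as.integer(v)
  }
  structure(x, class = c("pmc_coding", class(tibble())))
}

#' Read / write a coding matrix as CSV
#'
#' CSV layout: header row of secondary codes, first column `policy_id`, cells
#' 0/1, UTF-8. Lines starting with `#` are treated as metadata comments.
#'
#' @param file path to a CSV file.
#' @inheritParams as_coding_matrix
#' @return `read_coding_matrix()`: a validated `pmc_coding` tibble, row and
#'   column order preserved. `write_coding_matrix()`: `file`, invisibly.
#' @export
read_coding_matrix <- function(file, schema = default_schema()) {
  if (!file.exists(file)) {
    abort(sprintf("coding matrix file not found: %s", file), class = "pmcindex_io_error")
  }
  raw <- readr::read_csv(file, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  for (nm in setdiff(names(raw), "policy_id")) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("non-binary cell in '%s' at row %d, column '%s' (value: '%s')",
                    file, bad[1], nm, raw[[nm]][bad[1]]), class = "pmcindex_io_error")
    }
    raw[[nm]] <- v
  }
  as_coding_matrix(raw, schema)
}

#' @rdname read_coding_matrix
#' @param matrix a `pmc_coding` coding matrix.
#' @export
write_coding_matrix <- function(matrix, file) {
  readr::write_csv(as_tibble(matrix), file)
  invisible(file)
}

#' Per-indicator coverage rates
#'
#' Coverage of an indicator is the fraction of policies in the corpus coded 1
#' on it (e.g. 8 of 22 policies is a coverage rate of 36.36%).
#'
#' @param matrix a `pmc_coding` coding matrix.
#' @return a `pmc_coverage` tibble with `code`, `count`, `n`, `rate`.
#' @export
coverage_rates <- function(matrix) {
  codes <- setdiff(names(matrix), "policy_id")
  out <- tibble(
    code = codes,
    count = purrr::map_int(codes, ~ sum(matrix[[.x]])),
    n = nrow(matrix)
  ) |>
    mutate(rate = .data$count / .data$n)
  structure(out, class = c("pmc_coverage", class(tibble())))
}

#' Recover integer ones-counts from printed means
#'
#' Published summary tables print per-indicator means of binary codes to three
#' decimals; at a known corpus size these determine the integer count of ones.
#' The nearest integer is accepted only if it agrees with the printed mean to
#' 0.005, guarding against transcription errors.
#'
#' @param means numeric vector of printed means in `[0, 1]` (optionally named
#'   by indicator code, used in error messages).
#' @param n corpus size (policies).
#' @param tol maximum allowed |count/n - mean|.
#' @return integer vector of counts, names preserved.
#' @export
#' @examples
#' counts_from_means(c(`X6-1` = 0.364, `X6-2` = 0.364, `X6-3` = 0.636), 22)
counts_from_means <- function(means, n, tol = 0.005) {
  if (n < 1) abort("n must be >= 1", class = "pmcindex_input_error")
  if (any(means < 0 | means > 1)) {
    abort("means must lie in [0, 1]", class = "pmcindex_input_error")
  }
  counts <- as.integer(round(means * n))
  off <- abs(counts / n - means)
  bad <- which(off > tol + 1e-12)
  if (length(bad) > 0) {
    lab <- if (!is.null(names(means))) names(means)[bad] else as.character(bad)
    abort(sprintf(
      "mean(s) inconsistent with any integer count at n = %d: %s",
      n, paste(lab, collapse = ", ")), class = "pmcindex_reconstruction_error")
  }
  stats::setNames(counts, names(means))
}

#' Reconstruct a feasible binary coding matrix from marginals
#'
#' Given per-policy first-level dimension scores (exact thirds) and
#' per-secondary ones-counts, builds one feasible 0/1 matrix whose
#' within-dimension row sums equal 3 x score and whose column sums equal the
#' given counts. All index-level quantities depend only on these marginals, so
#' any feasible witness is equivalent; the witness returned is deterministic
#' (policies in input order; each policy's ones go first to columns whose
#' remaining demand equals the remaining number of policies — forced cells —
#' then to the largest remaining demand, ties in schema order).
#'
#' @param scores data frame: `policy_id` plus one column per dimension with
#'   values in \{0, 0.33, 0.67, 1\} (two-decimal thirds).
#' @param counts data frame with `code` and `count` for every schema secondary.
#' @param schema a `pmc_schema`.
#' @return a `pmc_coding` coding matrix.
#' @export
reconstruct_matrix <- function(scores, counts, schema = default_schema()) {
  scores <- as_tibble(scores)
  dims <- schema_dimensions(schema)
  out <- tibble(policy_id = scores$policy_id)
  for (d in dims$dimension) {
    sec <- schema$code[schema$dimension == d]
    t_dim <- length(sec)
    numer <- thirds_to_numerator(scores[[d]], denom = t_dim,
                                 what = sprintf("dimension %s", d))
    demand <- counts$count[match(sec, counts$code)]
    if (anyNA(demand)) {
      abort(sprintf("missing count(s) for dimension %s", d),
            class = "pmcindex_reconstruction_error")
    }
    if (sum(numer) != sum(demand)) {
      abort(sprintf(
        "infeasible marginals for dimension %s: row total %d != column total %d",
        d, sum(numer), sum(demand)), class = "pmcindex_reconstruction_error")
    }
    if (any(demand > nrow(scores)) || any(demand < 0)) {
      abort(sprintf("infeasible column count(s) for dimension %s", d),
            class = "pmcindex_reconstruction_error")
    }
    block <- matrix(0L, nrow = nrow(scores), ncol = t_dim, dimnames = list(NULL, sec))
    remaining <- demand
    for (p in seq_len(nrow(scores))) {
      r <- numer[p]
      rows_left <- nrow(scores) - p + 1L
      take <- integer(0)
      forced <- which(remaining >= rows_left)
      take <- head(forced, r)
      if (length(take) < r) {
        rest <- setdiff(order(-remaining, seq_along(remaining)), take)
        rest <- rest[remaining[rest] > 0]
        take <- c(take, head(rest, r - length(take)))
      }
      if (length(take) < r) {
        abort(sprintf("infeasible marginals for dimension %s (policy '%s')",
                      d, scores$policy_id[p]), class = "pmcindex_reconstruction_error")
      }
      block[p, take] <- 1L
      remaining[take] <- remaining[take] - 1L
    }
    # marginal exactness is asserted on every call
    stopifnot(all(rowSums(block) == numer), all(colSums(block) == demand))
    for (s in sec) out[[s]] <- block[, s]
  }
  as_coding_matrix(out, schema)
}
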