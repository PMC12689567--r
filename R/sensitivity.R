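#' Select sensitive indicators for perturbation
#'
#' Sensitivity analysis perturbs the indicators most likely to move the
#' corpus-average index: the lowest-average first-level dimensions and the
#' lowest-coverage second-level indicators. Ties are broken in schema order,
#' so the selection is deterministic.
#'
#' @param result a `pmc_evaluation`.
#' @param profile a `pmc_coverage` (or any tibble with `code`, `count`, `n`).
#' @param k_dimensions number of lowest-average dimensions to select.
#' @param k_secondaries optional cap on the number of selected secondaries
#'   (the lowest-coverage ones are kept; default all).
#' @return list with `dimensions` (character vector, schema order) and
#'   `secondaries` (tibble: `code`, `count`, `n`, `rate`), the
#'   minimum-coverage indicator(s) of each selected dimension (coverage ties
#'   within a dimension are all kept).
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' ev <- evaluate_from_first_level(fx$scores)
#' select_sensitive_indicators(ev, fx$counts)$secondaries$code
select_sensitive_indicators <- function(result, profile, k_dimensions = 3,
                                        k_secondaries = Inf) {
  dims <- result$dimension_averages
  if (k_dimensions > nrow(dims)) {
    warn(sprintf("k_dimensions capped at %d", nrow(dims)))
    k_dimensions <- nrow(dims)
  }
  low_dims <- dims$dimension[order(dims$average, seq_len(nrow(dims)))][seq_len(k_dimensions)]
  low_dims <- low_dims[order(match(low_dims, dims$dimension))] # report in schema order

  prof <- as_tibble(profile) |>
    mutate(rate = .data$count / .data$n,
           dimension = sub("-.*$", "", .data$code))
  low_sec <- prof |>
    filter(.data$dimension %in% low_dims) |>
    group_by(.data$dimension) |>
    filter(.data$rate == min(.data$rate)) |>
    ungroup() |>
    select("code", "count", "n", "rate")
  if (is.finite(k_secondaries) && k_secondaries < nrow(low_sec)) {
    low_sec <- low_sec[order(low_sec$rate, seq_len(nrow(low_sec))), ]
    low_sec <- low_sec[seq_len(k_secondaries), ]
    low_sec <- low_sec[order(match(low_sec$code, prof$code)), ]
  }
  list(dimensions = low_dims, secondaries = low_sec)
}

#' Apply a coverage scenario to one indicator
#'
#' The three scenarios mirror the standard stability check on binary scoring
#' systems: `baseline` leaves coverage unchanged, `partial` raises the target
#' indicator's coverage rate by a relative `increase` (default +30%), and
#' `full` raises it to 100% (every policy coded 1). Partial increases support
#' several allocation modes because a fractional count (e.g. 8 x 1.3 = 10.4
#' ones) cannot be realised by whole policies: `expected_value` keeps the
#' fractional count for analytic averaging (the default), `round_down` /
#' `round_up` flip whole policies, and `stochastic` flips a seeded random
#' subset.
#'
#' @param counts a coverage table (`code`, `count`, `n`), e.g. from
#'   [coverage_rates()] or the bundled fixture.
#' @param target indicator code to perturb.
#' @param scenario `"baseline"`, `"partial"`, or `"full"`.
#' @param increase relative coverage increase for partial scenarios.
#' @param mode allocation mode for partial scenarios.
#' @param seed integer seed, required for `mode = "stochastic"`.
#' @return the coverage table with the target's `count` modified (possibly
#'   fractional under `expected_value`).
#' @export
apply_scenario <- function(counts, target,
                           scenario = c("baseline", "partial", "full"),
                           increase = 0.30,
                           mode = c("expected_value", "round_down", "round_up", "stochastic"),
                           seed = NULL) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  counts <- as_tibble(counts)
  i <- match(target, counts$code)
  if (is.na(i)) {
    abort(sprintf("unknown indicator code: %s", target), class = "pmcindex_input_error")
  }
  if (scenario == "baseline") return(counts)
  n <- counts$n[i]
  cur <- counts$count[i]
  if (cur >= n) {
    warn(sprintf("indicator %s already saturated (coverage 100%%); scenario is a no-op", target))
    return(counts)
  }
  if (scenario == "full") {
    counts$count[i] <- n
    return(counts)
  }
  if (increase <= 0) abort("increase must be > 0", class = "pmcindex_input_error")
  raised <- min(n, cur * (1 + increase))
  counts$count[i] <- switch(mode,
    expected_value = raised,
    round_down = floor(raised),
    round_up = ceiling(raised),
    stochastic = {
      if (is.null(seed)) abort("stochastic mode requires a seed", class = "pmcindex_input_error")
      extra <- raised - cur
      add <- with_seed_local(seed, rbinom(1, size = n - cur, prob = min(1, extra / (n - cur))))
      cur + add
    }
  )
  counts
}

#' Run the three-scenario sensitivity table
#'
#' For each target indicator, recomputes the corpus-average PMC index under
#' the baseline, partial and full scenarios from the coverage counts alone:
#' the average index equals (total ones)/(T x n), so a coverage change of
#' delta ones shifts it by delta/(T x n). Grade changes are judged on the
#' displayed two-decimal values, matching how published sensitivity tables
#' flag them.
#'
#' @inheritParams apply_scenario
#' @param targets character vector of indicator codes.
#' @param scale a `pmc_grade_scale`.
#' @param t_per_dimension secondaries per dimension (T; 3 for the bundled
#'   schema).
#' @return a `pmc_sensitivity` tibble: `target`, `baseline`, `partial`,
#'   `full`, `baseline_grade`, `full_grade`, `grade_changed` (displayed
#'   two-decimal index values).
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' run_sensitivity(fx$counts, c("X4-2", "X6-1", "X6-2", "X8-3"))
run_sensitivity <- function(counts, targets, increase = 0.30,
                            mode = c("expected_value", "round_down", "round_up", "stochastic"),
                            seed = NULL, scale = default_grade_scale(),
                            t_per_dimension = 3) {
  mode <- match.arg(mode)
  counts <- as_tibble(counts)
  n <- unique(counts$n)
  if (length(n) != 1) {
    abort("all indicators must share one corpus size n", class = "pmcindex_input_error")
  }
  denom <- t_per_dimension * n
  avg <- function(tbl) sum(tbl$count) / denom

  baseline <- avg(counts)
  out <- purrr::map_dfr(targets, function(tg) {
    part <- avg(apply_scenario(counts, tg, "partial", increase = increase,
                               mode = mode, seed = seed))
    full <- avg(apply_scenario(counts, tg, "full"))
    tibble(target = tg, baseline = baseline, partial = part, full = full)
  }) |>
    mutate(
      baseline = round_half_up(.data$baseline, 2),
      partial = round_half_up(.data$partial, 2),
      full = round_half_up(.data$full, 2),
      baseline_grade = classify_grade(.data$baseline, scale),
      full_grade = classify_grade(.data$full, scale),
      grade_changed = .data$full_grade != .data$baseline_grade |
        classify_grade(.data$partial, scale) != .data$baseline_grade
    )
  structure(out, class = c("pmc_sensitivity", class(tibble())))
}
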