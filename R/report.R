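# Orchestration layer: one call evaluates a corpus and writes the standard
# file set; run_report() adds sensitivity, chi-square and (optionally)
# text-mining outputs plus a markdown report. Every output file carries a
# metadata comment header (tool version, config digest, seed).

meta_header <- function(config_digest, seed = NULL) {
  c(
    sprintf("# pmcindex %s", as.character(packageVersion("pmcindex"))),
    sprintf("# config_digest: %s", config_digest),
    if (!is.null(seed)) sprintf("# seed: %s", seed)
  )
}

write_csv_meta <- function(df, file, config_digest, seed = NULL) {
  writeLines(meta_header(config_digest, seed), file)
  readr::write_csv(df, file, append = TRUE, col_names = TRUE)
  invisible(file)
}

resolve_input <- function(fixture, scores, matrix, schema, scale) {
  if (identical(fixture, "mqimp") || isTRUE(fixture)) {
    fx <- mqimp_fixture()
    list(evaluation = evaluate_from_first_level(fx$scores, fx$schema, fx$scale),
         counts = fx$counts, schema = fx$schema, scale = fx$scale)
  } else if (!is.null(scores)) {
    ev <- evaluate_from_first_level(scores, schema, scale)
    list(evaluation = ev, counts = NULL, schema = schema, scale = scale)
  } else if (!is.null(matrix)) {
    m <- as_coding_matrix(matrix, schema)
    list(evaluation = evaluate_corpus(m, schema, scale),
         counts = coverage_rates(m), schema = schema, scale = scale)
  } else {
    abort("supply `fixture`, `scores`, or `matrix`", class = "pmcindex_input_error")
  }
}

#' Evaluate a corpus and write the standard output files
#'
#' Writes `scorecards.csv` (policy, per-dimension scores at two decimals,
#' Sum, Rank, Performance), `summary.json` (averages and grade histogram),
#' `radar.csv` and `surface.csv` to `output_dir`.
#'
#' @param output_dir directory for outputs (created if missing).
#' @param fixture `"mqimp"` to run the bundled 22-policy evaluation with zero
#'   external files; otherwise NULL.
#' @param scores optional first-level score table (see
#'   [evaluate_from_first_level()]).
#' @param matrix optional binary coding matrix (see [evaluate_corpus()]).
#' @param schema,scale schema and grade scale for non-fixture inputs.
#' @param threshold radar low-score flag threshold.
#' @param seed recorded in output metadata (no randomness in this stage).
#' @return the `pmc_evaluation`, invisibly.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile()
#' run_evaluation(out, fixture = "mqimp")
#' }
run_evaluation <- function(output_dir, fixture = NULL, scores = NULL, matrix = NULL,
                           schema = default_schema(), scale = default_grade_scale(),
                           threshold = 0.6, seed = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- resolve_input(fixture, scores, matrix, schema, scale)
  ev <- inp$evaluation
  digest <- rlang::hash(list(fixture = fixture, scores = scores, matrix = matrix,
                             threshold = threshold, seed = seed))

  dims <- ev$dimension_averages$dimension
  cards <- tidy(ev)
  cards_out <- dplyr::bind_cols(
    tibble(policy = cards$policy_id),
    as_tibble(lapply(cards[dims], fmt2)),
    tibble(Sum = fmt2(cards$pmc), Rank = cards$rank,
           Performance = as.character(cards$grade))
  )
  write_csv_meta(cards_out, file.path(output_dir, "scorecards.csv"), digest, seed)

  summary <- list(
    n_policies = ev$n_policies,
    average_pmc = ev$average_pmc_display,
    average_grade = as.character(ev$average_grade),
    dimension_averages = stats::setNames(
      as.list(round_half_up(ev$dimension_averages$average, 2)), dims),
    grade_histogram = stats::setNames(
      as.list(ev$grade_histogram$n_policies), as.character(ev$grade_histogram$grade)),
    tool_version = as.character(packageVersion("pmcindex")),
    config_digest = digest,
    seed = seed
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  write_csv_meta(radar_data(ev, threshold), file.path(output_dir, "radar.csv"),
                 digest, seed)
  write_csv_meta(surface_grid(average_surface(ev), resolution = 30),
                 file.path(output_dir, "surface.csv"), digest, seed)
  invisible(ev)
}

#' Full pipeline run with report
#'
#' Runs evaluation, surface/radar export, sensitivity scenarios and
#' within-dimension chi-square checks (plus text mining when a corpus is
#' given), writing `sensitivity.csv`, `chisq.csv`, `indicator_summary.csv`,
#' `term_freq.csv`/`network_edges.csv` and a human-readable `report.md`
#' alongside the [run_evaluation()] outputs. Reruns with the same inputs and
#' seed are byte-identical.
#'
#' @inheritParams run_evaluation
#' @param counts coverage counts for sensitivity/chi-square when not implied
#'   by `fixture` or `matrix`.
#' @param targets sensitivity targets; defaults to the lowest-coverage
#'   secondaries from [select_sensitive_indicators()].
#' @param corpus optional documents tibble (`doc_id`, `text`) for the
#'   text-mining stage.
#' @param stoplists optional stop-word sources for the text-mining stage.
#' @param increase,mode partial-scenario parameters (see [apply_scenario()]).
#' @return list with `evaluation`, `sensitivity`, `chisq`, invisibly.
#' @export
run_report <- function(output_dir, fixture = NULL, scores = NULL, matrix = NULL,
                       counts = NULL, targets = NULL, corpus = NULL, stoplists = NULL,
                       schema = default_schema(), scale = default_grade_scale(),
                       threshold = 0.6, increase = 0.30, mode = "expected_value",
                       seed = NULL) {
  ev <- run_evaluation(output_dir, fixture = fixture, scores = scores, matrix = matrix,
                       schema = schema, scale = scale, threshold = threshold, seed = seed)
  inp <- resolve_input(fixture, scores, matrix, schema, scale)
  counts <- counts %||% inp$counts
  digest <- rlang::hash(list(fixture = fixture, targets = targets, increase = increase,
                             mode = mode, threshold = threshold, seed = seed))

  sens <- chis <- NULL
  if (!is.null(counts)) {
    if (is.null(targets)) {
      sel <- select_sensitive_indicators(ev, counts)
      targets <- sel$secondaries$code
    }
    sens <- run_sensitivity(counts, targets, increase = increase, mode = mode,
                            seed = seed, scale = inp$scale)
    write_csv_meta(as_tibble(sens), file.path(output_dir, "sensitivity.csv"),
                   digest, seed)
    chis <- dimension_chisq(counts, inp$schema)
    write_csv_meta(chis, file.path(output_dir, "chisq.csv"), digest, seed)
    write_csv_meta(indicator_summary(counts),
                   file.path(output_dir, "indicator_summary.csv"), digest, seed)
  }
  if (!is.null(corpus)) {
    toks <- tokenize(corpus)
    if (!is.null(stoplists)) toks <- filter_stopwords(toks, stoplists)
    tf <- term_frequencies(toks)
    write_csv_meta(as_tibble(tf), file.path(output_dir, "term_freq.csv"), digest, seed)
    net <- cooccurrence_network(toks)
    write_csv_meta(net$edges, file.path(output_dir, "network_edges.csv"), digest, seed)
    export_wordcloud_data(tf, file.path(output_dir, "wordcloud.csv"))
  }

  lines <- c(
    "# PMC index evaluation report",
    "",
    sprintf("Tool: pmcindex %s; config digest %s%s",
            as.character(packageVersion("pmcindex")), digest,
            if (!is.null(seed)) sprintf("; seed %s", seed) else ""),
    "",
    sprintf("Policies evaluated: %d. Average PMC index: %.2f (%s).",
            ev$n_policies, ev$average_pmc_display, as.character(ev$average_grade)),
    "",
    "## Grade histogram",
    "",
    knit_table(ev$grade_histogram),
    "",
    "## Scorecards",
    "",
    knit_table({
      df <- tidy(ev)
      num <- vapply(df, is.numeric, logical(1)) & names(df) != "rank"
      df[num] <- lapply(df[num], fmt2)
      df
    }),
    ""
  )
  if (!is.null(sens)) {
    lines <- c(lines, "## Sensitivity scenarios", "", knit_table(as_tibble(sens)), "",
               "## Within-dimension chi-square", "", knit_table(chis), "")
  }
  writeLines(lines, file.path(output_dir, "report.md"))
  invisible(list(evaluation = ev, sensitivity = sens, chisq = chis))
}

# minimal pipe-table formatter for the markdown report
knit_table <- function(df) {
  df <- as_tibble(df)
  df[] <- lapply(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
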