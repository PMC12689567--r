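#' Load an indicator schema
#'
#' An indicator schema declares the hierarchical evaluation system: first-level
#' dimensions (e.g. `X4`, "Medical quality control dimension"), each holding an
#' ordered set of binary second-level indicators (e.g. `X4-2`, "Medical
#' security fund management and control"). The schema is data, not code, so the
#' toolkit generalises beyond the bundled 9-dimension x 3-indicator system.
#'
#' @param source path to a YAML or JSON schema file with top-level key
#'   `dimensions`, each entry `{code, name, secondaries: [{code, name,
#'   criterion}]}`, or an already-parsed list of that shape.
#' @return a `pmc_schema`: a tibble with one row per second-level indicator and
#'   columns `dimension`, `dimension_name`, `code`, `indicator_name`,
#'   `criterion`.
#' @export
#' @examples
#' schema <- default_schema()
#' dplyr::count(schema, dimension)
load_schema <- function(source) {
  spec <- if (is.character(source)) {
    if (!file.exists(source)) {
      abort(sprintf("schema file not found: %s", source), class = "pmcindex_io_error")
    }
    if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    source
  } else {
    abort("`source` must be a file path or a list", class = "pmcindex_input_error")
  }
  if (is.null(spec$dimensions) || length(spec$dimensions) == 0) {
    abort("schema must declare at least one dimension", class = "pmcindex_schema_error")
  }
  rows <- purrr::map_dfr(spec$dimensions, function(d) {
    if (is.null(d$code) || is.null(d$secondaries) || length(d$secondaries) == 0) {
      abort(sprintf("dimension '%s' is empty or missing a code", d$code %||% "<unnamed>"),
            class = "pmcindex_schema_error")
    }
    purrr::map_dfr(d$secondaries, function(s) {
      tibble(
        dimension = as.character(d$code),
        dimension_name = as.character(d$name %||% d$code),
        code = as.character(s$code %||% abort(
          sprintf("secondary in dimension '%s' missing a code", d$code),
          class = "pmcindex_schema_error")),
        indicator_name = as.character(s$name %||% s$code),
        criterion = as.character(s$criterion %||% NA_character_),
        weight = as.numeric(s$weight %||% 1)
      )
    })
  })
  validate_schema(rows)
}

validate_schema <- function(schema) {
  dup <- schema$code[duplicated(schema$code)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate secondary code(s): %s", paste(unique(dup), collapse = ", ")),
          class = "pmcindex_schema_error")
  }
  bad_prefix <- !stringr::str_starts(schema$code, stringr::fixed(schema$dimension))
  if (any(bad_prefix)) {
    abort(sprintf("secondary code(s) not prefixed by their dimension code: %s",
                  paste(schema$code[bad_prefix], collapse = ", ")),
          class = "pmcindex_schema_error")
  }
  structure(schema, class = c("pmc_schema", class(tibble())))
}

#' @rdname load_schema
#' @details `default_schema()` returns the bundled system for Chinese national
#'   medical-quality intelligent-management policies: nine dimensions (policy
#'   objectives, entities, intelligent technology application, medical quality
#'   control, control measures, data support, implementation guarantee, policy
#'   audience, policy timeliness), three binary criteria each.
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "mqimp_schema.yaml", package = "pmcindex"))
}

#' Dimension-level view of a schema
#'
#' @param schema a `pmc_schema`.
#' @return tibble with `dimension`, `dimension_name`, `n_secondary` (the
#'   divisor T used in dimension scoring).
#' @export
schema_dimensions <- function(schema) {
  schema |>
    group_by(dimension, dimension_name) |>
    summarise(n_secondary = dplyr::n(), .groups = "drop") |>
    # preserve declaration order, not alphabetical
    arrange(match(dimension, unique(schema$dimension)))
}

#' Grade scale for PMC index values
#'
#' The six consistency categories partition the index range: intervals are
#' lower-inclusive / upper-exclusive except the top band, which is closed, so
#' the maximum attainable index still grades (8.00 is Perfect, 5.00 is Good).
#'
#' @param source optional path to a YAML/JSON file with key `bands:
#'   [{label, lower, upper}]`; default is the bundled six-band scale
#'   (Poor < 4, Acceptable < 5, Good < 6, Excellent < 7, Superb < 8,
#'   Perfect <= 9).
#' @return a `pmc_grade_scale`: tibble with `label`, `lower`, `upper`, bands in
#'   ascending order.
#' @export
#' @examples
#' classify_grade(c(8, 6.29, 0, 7), default_grade_scale())
default_grade_scale <- function(source = NULL) {
  source <- source %||% system.file("extdata", "grade_scale.yaml", package = "pmcindex")
  spec <- if (is.character(source)) yaml::read_yaml(source) else source
  bands <- purrr::map_dfr(spec$bands, ~ tibble(
    label = as.character(.x$label), lower = as.numeric(.x$lower), upper = as.numeric(.x$upper)
  ))
  bands <- arrange(bands, lower)
  gaps <- bands$lower[-1] != bands$upper[-nrow(bands)]
  if (any(gaps)) {
    abort("grade bands must be contiguous and non-overlapping", class = "pmcindex_schema_error")
  }
  structure(bands, class = c("pmc_grade_scale", class(tibble())))
}

#' Classify PMC index values into grade bands
#'
#' @param pmc numeric vector of index values in `[0, max(scale$upper)]`.
#' @param scale a `pmc_grade_scale`; defaults to the bundled six-band scale.
#' @return a factor with levels in band order (lowest first), one label per
#'   input value.
#' @export
classify_grade <- function(pmc, scale = default_grade_scale()) {
  lo <- min(scale$lower)
  hi <- max(scale$upper)
  if (any(is.na(pmc)) || any(pmc < lo - 1e-9) || any(pmc > hi + 1e-9)) {
    abort(sprintf("PMC index values must lie in [%g, %g]", lo, hi),
          class = "pmcindex_range_error")
  }
  # lower-inclusive, upper-exclusive; closed top band
  idx <- findInterval(pmin(pmc, hi), scale$lower)
  idx[pmc >= hi] <- nrow(scale)
  factor(scale$label[idx], levels = scale$label, ordered = TRUE)
}
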