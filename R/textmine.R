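# Tokenizer plugin registry. The default "unicode" tokenizer segments on
# non-letter characters, which suits space-delimited text; corpora needing
# dictionary-based segmentation (e.g. Chinese policy texts with a custom
# medical lexicon) can register an external segmenter under a new id.
the_tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer plugin
#'
#' @param id plugin identifier.
#' @param fun function `(text, lexicon)` returning a character vector of
#'   tokens; it must never split a protected lexicon term.
#' @return `id`, invisibly.
#' @export
register_tokenizer <- function(id, fun) {
  stopifnot(is.character(id), is.function(fun))
  assign(id, fun, envir = the_tokenizers)
  invisible(id)
}

default_unicode_tokenizer <- function(text, lexicon = character()) {
  placeholder <- function(i) sprintf("\x1f%d\x1f", i)
  # protect multi-word lexicon terms before splitting (longest first)
  lexicon <- lexicon[order(-nchar(lexicon))]
  for (i in seq_along(lexicon)) {
    text <- stringr::str_replace_all(text, stringr::fixed(lexicon[i]), placeholder(i))
  }
  tokens <- unlist(stringr::str_split(text, "[^\\p{L}\\p{N}\x1f]+"))
  tokens <- tokens[tokens != ""]
  # tokens containing digits are dropped wholesale: numbers carry no policy
  # semantics and partial stripping would invent tokens
  keep <- !stringr::str_detect(tokens, "\\p{N}") | stringr::str_detect(tokens, "\x1f")
  tokens <- tokens[keep]
  for (i in seq_along(lexicon)) {
    tokens[tokens == sprintf("\x1f%d\x1f", i)] <- lexicon[i]
  }
  tokens
}

get_tokenizer <- function(id) {
  if (!exists(id, envir = the_tokenizers)) {
    abort(sprintf("unknown tokenizer plugin: %s", id), class = "pmcindex_input_error")
  }
  get(id, envir = the_tokenizers)
}

#' Tokenize documents
#'
#' Splits raw text into tokens with a registered tokenizer plugin, protecting
#' multi-word lexicon terms (domain vocabulary such as "big data" stays one
#' token) and dropping punctuation, digits and special characters.
#'
#' @param docs tibble with `doc_id` and `text` columns (one row per policy
#'   document), or a single character string.
#' @param lexicon character vector of protected multi-word terms.
#' @param tokenizer plugin id (default `"unicode"`).
#' @return long tibble with `doc_id`, `token` (one row per token occurrence,
#'   document order preserved). For a single string, a character vector.
#' @export
#' @examples
#' tokenize("big data improves big data quality", lexicon = "big data")
tokenize <- function(docs, lexicon = character(), tokenizer = "unicode") {
  fun <- get_tokenizer(tokenizer)
  if (is.character(docs)) {
    if (length(docs) != 1) {
      abort("pass multiple documents as a tibble with doc_id and text",
            class = "pmcindex_input_error")
    }
    return(fun(docs, lexicon))
  }
  docs <- as_tibble(docs)
  if (anyDuplicated(docs$doc_id)) {
    abort("doc_id values must be unique", class = "pmcindex_input_error")
  }
  purrr::map_dfr(seq_len(nrow(docs)), function(i) {
    toks <- fun(docs$text[i], lexicon)
    if (length(toks) == 0) return(tibble(doc_id = character(), token = character()))
    tibble(doc_id = docs$doc_id[i], token = toks)
  })
}

#' Remove stop words
#'
#' @param tokens a tokens tibble (`doc_id`, `token`) or character vector.
#' @param stoplists one or more stop-word sources: character vectors of words
#'   and/or paths to plain-text files (one word per line); their union is
#'   removed.
#' @param fold_case compare case-insensitively (default TRUE).
#' @return tokens with stop words removed, same shape as the input.
#' @export
filter_stopwords <- function(tokens, stoplists, fold_case = TRUE) {
  if (!is.list(stoplists)) stoplists <- list(stoplists)
  words <- unlist(purrr::map(stoplists, function(s) {
    if (length(s) == 1 && !is.na(s) && file.exists(s)) {
      readr::read_lines(s)
    } else {
      s
    }
  }))
  words <- words[words != ""]
  if (fold_case) words <- stringr::str_to_lower(words)
  drop <- function(v) {
    key <- if (fold_case) stringr::str_to_lower(v) else v
    v[!(key %in% words)]
  }
  if (is.character(tokens)) return(drop(tokens))
  keep_key <- if (fold_case) stringr::str_to_lower(tokens$token) else tokens$token
  tokens[!(keep_key %in% words), ]
}

#' Ranked term-frequency table
#'
#' @param tokens tokens tibble (`doc_id`, `token`) or character vector.
#' @param top_k number of top terms to keep (default all).
#' @param count_mode `"tokens"` counts every occurrence; `"documents"` counts
#'   the number of documents containing the term once each.
#' @return a `pmc_termfreq` tibble: `rank`, `term`, `frequency`, frequencies
#'   non-increasing, ties broken lexicographically.
#' @export
#' @examples
#' term_frequencies(c("c", "c", "c", "b", "b", "a"))
term_frequencies <- function(tokens, top_k = Inf,
                             count_mode = c("tokens", "documents")) {
  count_mode <- match.arg(count_mode)
  if (top_k < 1) abort("top_k must be >= 1", class = "pmcindex_input_error")
  if (is.character(tokens)) {
    tokens <- tibble(doc_id = "doc1", token = tokens)
  }
  if (nrow(tokens) == 0) {
    return(structure(tibble(rank = integer(), term = character(), frequency = integer()),
                     class = c("pmc_termfreq", class(tibble()))))
  }
  counted <- if (count_mode == "documents") {
    dplyr::distinct(tokens, .data$doc_id, .data$token)
  } else {
    tokens
  }
  tab <- counted |>
    count(term = .data$token, name = "frequency") |>
    arrange(desc(.data$frequency), .data$term) |>
    mutate(rank = row_number()) |>
    select("rank", "term", "frequency")
  if (is.finite(top_k)) tab <- head(tab, top_k)
  structure(tab, class = c("pmc_termfreq", class(tibble())))
}

#' Term co-occurrence network
#'
#' Builds the undirected semantic network of a corpus: nodes are terms with
#' their total frequency; an edge's weight is the number of documents (or
#' sliding token windows of length `window`) in which both terms appear.
#'
#' @param tokens tokens tibble (`doc_id`, `token`).
#' @param window `"document"` (default) for document-level co-occurrence, or
#'   an integer window length >= 2 for sliding token windows within each
#'   document.
#' @param min_weight prune edges below this weight (nodes are retained).
#' @return a `pmc_network` list with tibbles `nodes` (`term`, `frequency`)
#'   and `edges` (`term_a`, `term_b`, `weight`), pairs stored with
#'   `term_a < term_b`.
#' @export
cooccurrence_network <- function(tokens, window = "document", min_weight = 1) {
  tokens <- as_tibble(tokens)
  nodes <- tokens |>
    count(term = .data$token, name = "frequency") |>
    arrange(desc(.data$frequency), .data$term)

  units <- if (identical(window, "document")) {
    split(tokens$token, tokens$doc_id)
  } else {
    if (!is.numeric(window) || window < 2) {
      abort("window must be \"document\" or an integer >= 2", class = "pmcindex_input_error")
    }
    unlist(lapply(split(tokens$token, tokens$doc_id), function(toks) {
      if (length(toks) <= window) return(list(toks))
      lapply(seq_len(length(toks) - window + 1), function(i) toks[i:(i + window - 1)])
    }), recursive = FALSE)
  }
  pair_counts <- list()
  for (u in units) {
    terms <- sort(unique(u))
    if (length(terms) < 2) next
    idx <- utils::combn(terms, 2)
    keys <- paste(idx[1, ], idx[2, ], sep = "\x1f")
    for (k in keys) pair_counts[[k]] <- (pair_counts[[k]] %||% 0L) + 1L
  }
  edges <- if (length(pair_counts) == 0) {
    tibble(term_a = character(), term_b = character(), weight = integer())
  } else {
    parts <- stringr::str_split_fixed(names(pair_counts), "\x1f", 2)
    tibble(term_a = parts[, 1], term_b = parts[, 2],
           weight = as.integer(unlist(pair_counts))) |>
      filter(.data$weight >= min_weight) |>
      arrange(desc(.data$weight), .data$term_a, .data$term_b)
  }
  structure(list(nodes = nodes, edges = edges), class = "pmc_network")
}

#' @export
print.pmc_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d terms, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export word-cloud weights
#'
#' @param table a `pmc_termfreq` table.
#' @param file CSV destination (`term`, `weight`).
#' @return `file`, invisibly.
#' @export
export_wordcloud_data <- function(table, file) {
  readr::write_csv(select(as_tibble(table), term = "term", weight = "frequency"), file)
  invisible(file)
}
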