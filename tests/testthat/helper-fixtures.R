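# Build a minimal schema programmatically: k dimensions ("D1", ...) with t
# secondaries each ("D1-1", ...).
mini_schema <- function(k = 2, t = 2) {
  load_schema(list(dimensions = lapply(seq_len(k), function(i) {
    code <- paste0("D", i)
    list(code = code, name = paste("dim", i),
         secondaries = lapply(seq_len(t), function(j) {
           list(code = paste0(code, "-", j), name = paste("sec", i, j),
                criterion = "synthetic")
         }))
  })))
}

# A tiny all-specified coding matrix on the default 9 x 3 schema.
constant_matrix <- function(n = 2, value = 1, schema = default_schema()) {
  out <- tibble::tibble(policy_id = paste0("Q", seq_len(n)))
  for (code in schema$code) out[[code]] <- as.integer(value)
  as_coding_matrix(out, schema)
}

# First-principles Pearson statistic, kept independent of pearson_chisq().
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}
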