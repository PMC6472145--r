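# Shared fixtures: a tiny journal registry, a record-row builder, and
# random record generators for property tests. Everything is built in code.

tiny_registry <- function() {
  read_journal_registry(data.frame(
    raw_name = c("Journal of Applied Things",
                 "J Applied Things (old)",
                 "Quarterly of Basic Things",
                 "General Omnibus Review"),
    canonical_name = c("Journal of Applied Things",
                       "Journal of Applied Things",
                       "Quarterly of Basic Things",
                       "General Omnibus Review"),
    disciplines = c("applied;shared", "applied;shared", "basic;shared", ""),
    core_only = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ))
}

# minimal record row with sensible defaults, overridable per field
make_record <- function(article_id = "a1", doi = "10.1/x",
                        journal_raw = "Journal of Applied Things",
                        journal_canonical = journal_raw,
                        year = 2000L, raw = "p = .06", comparison = "=",
                        value_text = ".06", value = 0.06, offset = 0L,
                        context_before = "", context_after = "") {
  data.frame(article_id = article_id, doi = doi, journal_raw = journal_raw,
             journal_canonical = journal_canonical, year = year, raw = raw,
             comparison = comparison, value_text = value_text, value = value,
             offset = offset, context_before = context_before,
             context_after = context_after, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# random records for round-trip / oracle property tests
random_records <- function(n, seed = 42) {
  withr::local_seed(seed)
  vt <- sprintf("%.3f", runif(n, 0.001, 0.999))
  data.frame(
    article_id = sprintf("a%04d", sample.int(max(2, n %/% 3), n, TRUE)),
    doi = ifelse(runif(n) < 0.95, sprintf("10.1/d%04d", seq_len(n)),
                 NA_character_),
    journal_raw = sample(c("Journal of Applied Things",
                           "Quarterly of Basic Things"), n, TRUE),
    journal_canonical = NA_character_,
    year = sample(1985:2016, n, TRUE),
    raw = paste0("p = ", vt),
    comparison = sample(c("<", ">", "=", "<=", ">="), n, TRUE),
    value_text = vt,
    value = as.numeric(vt),
    offset = sample.int(10000L, n),
    context_before = vapply(seq_len(n), function(i) {
      paste(sample(c("alpha", "beta, with \"quotes\"", "line\nbreak",
                     "commas, commas", "café text"),
                   sample(1:4, 1), TRUE), collapse = " ")
    }, character(1)),
    context_after = "trailing context",
    stringsAsFactors = FALSE
  )
}
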