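# Journal standardisation, metadata completion, filter cascade, sampling.

test_that("standardize_journal maps aliases, is idempotent, warns on unknown", {
  reg <- tiny_registry()
  expect_equal(standardize_journal("J Applied Things (old)", reg),
               "Journal of Applied Things")
  expect_equal(standardize_journal("Journal of Applied Things", reg),
               "Journal of Applied Things")
  # case- and whitespace-insensitive lookup
  expect_equal(standardize_journal("  journal of  applied things ", reg),
               "Journal of Applied Things")
  expect_warning(out <- standardize_journal("Unknown Gazette", reg),
                 "Unknown Gazette")
  expect_equal(out, "Unknown Gazette")
})

test_that("complete_metadata fills only gaps and isolates resolver failures", {
  rec <- make_records(
    make_record(article_id = "a1", doi = "10.1/known", year = NA_integer_),
    make_record(article_id = "a2", doi = "10.1/known",
                journal_raw = NA_character_, year = 1999L),
    make_record(article_id = "a3", doi = "10.1/fails", year = NA_integer_),
    make_record(article_id = "a4", doi = NA_character_, year = NA_integer_),
    make_record(article_id = "a5", doi = "10.1/other", year = 2005L)
  )
  resolver <- function(doi) {
    if (doi == "10.1/fails") stop("resolver down")
    list(journal = "Quarterly of Basic Things", year = 1988L)
  }
  res <- suppressMessages(complete_metadata(rec, resolver))
  out <- res$records
  expect_equal(out$year[1], 1988L)                      # gap filled
  expect_equal(out$journal_raw[2], "Quarterly of Basic Things")
  expect_equal(out$year[2], 1999L)                      # never overwritten
  expect_true(is.na(out$year[3]))                       # failure isolated
  expect_true(is.na(out$year[4]))                       # no DOI, untouched
  expect_equal(out$year[5], 2005L)                      # complete, unchanged
  expect_equal(res$n_resolved, 2L)
})

test_that("filter cascade stages are ordered, exclusive, and sum to n_input", {
  reg <- tiny_registry()
  rec <- make_records(
    make_record(article_id = "m", doi = NA_character_,
                journal_raw = NA_character_, journal_canonical = NA_character_,
                year = NA_integer_),                        # missing_metadata
    make_record(article_id = "n", value_text = ".", value = NA_real_),
    make_record(article_id = "c", journal_raw = "General Omnibus Review",
                journal_canonical = "General Omnibus Review"), # core journal
    make_record(article_id = "o1", value_text = ".04", value = 0.04),
    make_record(article_id = "o2", value_text = ".05", value = 0.05),
    make_record(article_id = "o3", value_text = ".2", value = 0.2),
    make_record(article_id = "o4", value_text = "1.2", value = 1.2),
    make_record(article_id = "r1", value_text = ".06", value = 0.06),
    make_record(article_id = "r2", value_text = ".10", value = 0.10),
    make_record(article_id = "r3", value_text = ".099", value = 0.099)
  )
  flt <- apply_filters(rec, reg)
  rp <- flt$report
  expect_equal(rp$n_input, 10L)
  expect_equal(rp$n_missing_metadata, 1L)
  expect_equal(rp$n_nonnumeric, 1L)
  expect_equal(rp$n_core_excluded, 1L)
  expect_equal(rp$n_out_of_range, 4L)
  expect_equal(rp$n_retained, 3L)
  expect_equal(rp$n_missing_metadata + rp$n_nonnumeric + rp$n_core_excluded +
                 rp$n_out_of_range + rp$n_retained, rp$n_input)
  expect_setequal(flt$retained$article_id, c("r1", "r2", "r3"))
  # .05 dropped whatever the sign; .10 and probable misreport .099 retained
  expect_equal(flt$records$filter_status[flt$records$article_id == "o2"],
               "out_of_range")
})

test_that("filtering is idempotent on its own retained output", {
  reg <- tiny_registry()
  res <- run_pipeline(list(simulate = list(n_articles = 40, seed = 3),
                           seed = 3))
  retained <- res$records[res$records$filter_status == "retained", ]
  reg2 <- sim_registry(sim_config(n_articles = 1, seed = 3))
  again <- apply_filters(retained, reg2)
  expect_equal(again$report$n_retained, nrow(retained))
  expect_equal(again$report$n_input, nrow(retained))
})

test_that("range filter boundary is exact on a fine grid (property)", {
  vals <- sprintf("%.6f", seq(0.049990, 0.050010, by = 1e-6))
  vals <- c(vals, sprintf("%.6f", seq(0.099990, 0.100010, by = 1e-6)))
  inr <- value_in_range(vals)
  num <- as.numeric(vals)
  # oracle on the printed grid: strictly above .05, at most .10
  expect_equal(inr, num > 0.05 + 1e-12 & num <= 0.10 + 1e-12)
})

test_that("assign_disciplines handles multi-membership and unknowns", {
  reg <- tiny_registry()
  rec <- make_records(
    make_record(article_id = "a1"),                      # applied + shared
    make_record(article_id = "a2",
                journal_raw = "Quarterly of Basic Things",
                journal_canonical = "Quarterly of Basic Things"),
    make_record(article_id = "a3", journal_raw = "Mystery Review",
                journal_canonical = "Mystery Review")
  )
  out <- suppressWarnings(assign_disciplines(rec, reg))
  expect_true(out$disc_applied[1] && out$disc_shared[1] && !out$disc_basic[1])
  expect_true(out$disc_basic[2] && out$disc_shared[2] && !out$disc_applied[2])
  expect_false(any(out$disc_applied[3], out$disc_basic[3], out$disc_shared[3]))
  expect_warning(assign_disciplines(rec, reg), "Mystery Review")
})

test_that("stratified sample sizes follow half-up rounding per stratum", {
  rec <- do.call(rbind, lapply(1:100, function(i) {
    make_record(article_id = paste0("a", i))
  }))
  rec2 <- do.call(rbind, lapply(1:5, function(i) {
    make_record(article_id = paste0("b", i),
                journal_raw = "Quarterly of Basic Things",
                journal_canonical = "Quarterly of Basic Things")
  }))
  both <- rbind(rec, rec2)
  smp <- stratified_sample(both, fraction = 0.06, seed = 9)
  tab <- table(smp$journal_canonical)
  expect_equal(unname(tab[["Journal of Applied Things"]]), 6L)
  # round(0.3) -> 0 rows from the 5-row stratum
  expect_false("Quarterly of Basic Things" %in% names(tab))
  # determinism
  smp2 <- stratified_sample(both, fraction = 0.06, seed = 9)
  expect_identical(smp, smp2)
  # half-up: 25 rows at 6% -> 1.5 -> 2
  rec25 <- both[1:25, ]
  expect_equal(nrow(stratified_sample(rec25, 0.06, seed = 1)), 2L)
})
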