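# Outcome definitions, denominators, confidence intervals, rollups.

# independent brute-force oracle for one group of labeled rows
oracle_pct <- function(rows) {
  inr <- rows$in_range %in% TRUE
  marg <- inr & rows$is_marginal %in% TRUE
  arts <- unique(rows$article_id)
  list(
    pct_marginal = if (sum(inr) > 0) 100 * sum(marg) / sum(inr) else NA_real_,
    pct_articles_marginal =
      100 * length(unique(rows$article_id[marg])) / length(arts),
    pvalues_per_article = nrow(rows) / length(arts)
  )
}

labeled_fixture <- function(n = 400, seed = 5) {
  withr::local_seed(seed)
  journals <- c("Journal of Applied Things", "Quarterly of Basic Things")
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- sample(journals, 1)
    make_record(article_id = paste0("a", sample.int(60, 1)),
                journal_raw = j, journal_canonical = j,
                year = sample(1990:1995, 1))
  }))
  rec$filter_status <- sample(c("retained", "out_of_range"), n, TRUE,
                              prob = c(0.3, 0.7))
  rec$in_range <- rec$filter_status == "retained"
  rec$is_marginal <- ifelse(rec$in_range, runif(n) < 0.4, NA)
  suppressWarnings(assign_disciplines(rec, tiny_registry()))
}

test_that("per-article rollup flags are nested", {
  rec <- make_records(
    make_record(article_id = "a1"), make_record(article_id = "a1"),
    make_record(article_id = "a1"),
    make_record(article_id = "a2", value_text = ".3", value = 0.3),
    make_record(article_id = "a3"), make_record(article_id = "a3")
  )
  rec$in_range <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  rec$is_marginal <- c(TRUE, FALSE, FALSE, NA, FALSE, FALSE)
  roll <- per_article_rollup(rec)
  expect_equal(roll$article_id, c("a1", "a2", "a3"))
  expect_equal(roll$has_p, c(TRUE, TRUE, TRUE))
  expect_equal(roll$has_inrange, c(TRUE, FALSE, TRUE))
  expect_equal(roll$has_marginal, c(TRUE, FALSE, FALSE))
  expect_true(all(roll$has_marginal <= roll$has_inrange))
  expect_true(all(roll$has_inrange <= roll$has_p))
})

test_that("group percentages match the brute-force oracle (property)", {
  rec <- labeled_fixture()
  st <- summarize_groups(rec, by = "overall")
  oc <- oracle_pct(rec)
  expect_equal(st$pct_marginal, oc$pct_marginal, tolerance = 1e-12)
  expect_equal(st$pct_articles_marginal, oc$pct_articles_marginal,
               tolerance = 1e-12)
  expect_equal(st$pvalues_per_article, oc$pvalues_per_article,
               tolerance = 1e-12)

  stj <- summarize_groups(rec, by = "journal")
  for (g in stj$group) {
    ocj <- oracle_pct(rec[rec$journal_canonical == g, ])
    expect_equal(stj$pct_marginal[stj$group == g], ocj$pct_marginal,
                 tolerance = 1e-12, info = g)
  }
})

test_that("discipline grouping uses multi-membership", {
  rec <- labeled_fixture()
  std <- summarize_groups(rec, by = "discipline")
  ov <- summarize_groups(rec, by = "overall")
  # every journal belongs to "shared", so that discipline equals overall
  expect_equal(std$n_pvalues[std$group == "shared"], ov$n_pvalues)
  # multi-membership: discipline totals sum to at least the overall total
  expect_gte(sum(std$n_pvalues), ov$n_pvalues)
  # rows counted fully in each member discipline
  applied <- oracle_pct(rec[rec$disc_applied, ])
  expect_equal(std$pct_marginal[std$group == "applied"],
               applied$pct_marginal, tolerance = 1e-12)
})

test_that("article-level denominator is all articles with p-values", {
  rec <- labeled_fixture()
  st <- summarize_groups(rec, by = "overall")
  n_all_articles <- length(unique(rec$article_id))
  expect_equal(st$n_articles_with_p, n_all_articles)
  expect_gte(n_all_articles, st$n_articles_with_inrange)
  expect_equal(st$pct_articles_marginal,
               100 * st$n_articles_marginal / n_all_articles)
})

test_that("empty in-range cell yields missing percentage, never zero", {
  rec <- make_records(make_record(article_id = "a1", value_text = ".3",
                                  value = 0.3))
  rec$filter_status <- "out_of_range"
  rec$in_range <- FALSE
  rec$is_marginal <- NA
  st <- summarize_groups(rec, by = "overall")
  expect_true(is.na(st$pct_marginal))
  expect_true(is.na(st$pct_marginal_lower))
  expect_equal(st$n_pvalues, 1L)
})

test_that("wald interval has frozen closed-form values and sane degenerates", {
  # frozen from z = qnorm(.975) arithmetic done by hand:
  # 0.5 +/- 1.9599640*sqrt(0.25/100) = 0.5 +/- 0.0979982
  ci <- wald_ci(0.5, 100)
  expect_equal(ci$lower, 40.20018, tolerance = 1e-6)
  expect_equal(ci$upper, 59.79982, tolerance = 1e-6)
  expect_equal(unlist(wald_ci(0, 50)), c(lower = 0, upper = 0))
  expect_equal(unlist(wald_ci(1, 50)), c(lower = 100, upper = 100))
  expect_true(all(is.na(wald_ci(0.5, 0))))
})

test_that("CI width shrinks with n and bounds stay in [0, 100] (property)", {
  withr::local_seed(11)
  for (i in 1:25) {
    p <- runif(1, 0.01, 0.99)
    ns <- sort(sample(2:5000, 4))
    w <- wald_ci(p, ns)$upper - wald_ci(p, ns)$lower
    expect_true(all(diff(w) < 0))
    ci <- wald_ci(p, ns)
    expect_true(all(ci$lower >= 0 & ci$upper <= 100))
    expect_true(all(ci$lower <= 100 * p & 100 * p <= ci$upper))
    wl <- wilson_ci(p, ns)
    expect_true(all(wl$lower >= 0 & wl$upper <= 100))
  }
})

test_that("wilson differs from wald but agrees for large n", {
  wa <- wald_ci(0.4, 1e6)
  wi <- wilson_ci(0.4, 1e6)
  expect_equal(wa$lower, wi$lower, tolerance = 1e-3)
  wa2 <- wald_ci(0.05, 20)
  wi2 <- wilson_ci(0.05, 20)
  expect_gt(abs(wa2$lower - wi2$lower), 0.5)
})

test_that("per-year cells exclude unresolved years but all-years keep them", {
  rec <- labeled_fixture(100)
  rec$year[1:10] <- NA_integer_
  expect_message(st <- summarize_groups(rec, by = "overall", per_year = TRUE),
                 "without year")
  allyears <- st[is.na(st$year), ]
  expect_equal(allyears$n_pvalues, 100L)
  expect_equal(sum(st$n_pvalues[!is.na(st$year)]), 90L)
})

test_that("group stats from printed counts reproduce ratio arithmetic", {
  gs <- group_stats_from_counts(n_articles_with_p = 100, n_pvalues = 1759,
                                n_inrange = 96, n_marginal = 38,
                                n_articles_marginal = 20)
  expect_equal(gs$pvalues_per_article, 17.59)
  expect_equal(gs$inrange_per_article, 0.96)
  expect_equal(gs$pct_marginal, 100 * 38 / 96)
  expect_equal(gs$pct_articles_marginal, 20)
  # half-up (away from zero) on binary-exact halves; base round() gives 2/-2
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(c(2.5, -2.5), 0), c(3, -3))
})
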