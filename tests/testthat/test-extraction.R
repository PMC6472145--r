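# p-value grammar, value parsing, context capture, exact range boundaries.

test_that("grammar matches the canonical report forms", {
  m <- extract_pvalues("the effect was marginal, p = .06, in study 2")
  expect_equal(nrow(m), 1L)
  expect_equal(m$raw, "p = .06")
  expect_equal(m$comparison, "=")
  expect_equal(m$value, 0.06)
  expect_match(m$context_before, "marginal, $")
  expect_match(m$context_after, "^, in study 2$")

  cases <- data.frame(
    text = c("p=.048 was found", "P < .05 overall", "p<.05", "*p* = .072",
             "p  =  0.3", "p = 6e-05 there", "p =< .05", "p >= .10",
             "p ≤ .05"),
    raw = c("p=.048", "P < .05", "p<.05", "p* = .072", "p  =  0.3",
            "p = 6e-05", "p =< .05", "p >= .10", "p ≤ .05"),
    comparison = c("=", "<", "<", "=", "=", "=", "<=", ">=", "<="),
    value = c(0.048, 0.05, 0.05, 0.072, 0.3, 6e-05, 0.05, 0.10, 0.05),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    m <- extract_pvalues(cases$text[i])
    expect_equal(m$raw, cases$raw[i], info = cases$text[i])
    expect_equal(m$comparison, cases$comparison[i], info = cases$text[i])
    expect_equal(m$value, cases$value[i], info = cases$text[i])
  }
})

test_that("plural ps is skipped by default and matched via the flag", {
  txt <- "results (all ps > .30) and p<.05 and p = .072"
  m <- extract_pvalues(txt)
  expect_equal(m$raw, c("p<.05", "p = .072"))
  m2 <- extract_pvalues(txt, match_plural_ps = TRUE)
  expect_equal(m2$raw, c("ps > .30", "p<.05", "p = .072"))
})

test_that("tokens embedded in words or identifiers do not match", {
  expect_equal(nrow(extract_pvalues("group = .05 and prep: <.05")), 0L)
  expect_equal(nrow(extract_pvalues("x2p = nothing numeric")), 0L)
})

test_that("extended signs can be disabled", {
  txt <- "p <= .05 and p < .01"
  m <- extract_pvalues(txt, extended_signs = FALSE)
  expect_equal(m$raw, "p < .01")
})

test_that("broken numbers are emitted with the invalid marker", {
  m <- extract_pvalues("difference was null, p = . End of story")
  expect_equal(nrow(m), 1L)
  expect_true(is.na(m$value))
  expect_equal(m$value_text, ".")
})

test_that("parse_value handles printed forms and rejects the rest", {
  expect_equal(parse_value(c(".048", "0.05", "1.2", "6e-05", "12")),
               c(0.048, 0.05, 1.2, 6e-05, 12))
  expect_true(all(is.na(parse_value(c(".", "", "abc", "1.2.3")))))
})

test_that("contexts truncate at document boundaries and reconstruct the source", {
  txt <- paste0(strrep("a", 9), " p = .06", strrep("b", 50))
  m <- extract_pvalues(txt)
  expect_equal(nchar(m$context_before), 10L)
  expect_equal(nchar(m$context_after), 50L)
  # context reconstruction invariant on a multi-mention document
  txt2 <- paste0(strrep("x ", 150), "p < .08 middle filler ", strrep("y ", 20),
                 "then p = .03 and finally p = .10", strrep(" z", 140))
  m2 <- extract_pvalues(txt2)
  expect_equal(nrow(m2), 3L)
  for (i in seq_len(nrow(m2))) {
    start <- m2$offset[i] + 1L
    pre <- substr(txt2, max(1L, start - 200L), start - 1L)
    post <- substr(txt2, start + nchar(m2$raw[i]),
                   start + nchar(m2$raw[i]) + 199L)
    expect_identical(pre, m2$context_before[i])
    expect_identical(post, m2$context_after[i])
    expect_identical(substr(txt2, start, start + nchar(m2$raw[i]) - 1L),
                     m2$raw[i])
  }
})

test_that("shrinking the window changes contexts but never the mention count", {
  txt <- paste0(strrep("pad ", 100), "p = .06 and p < .03 ", strrep("pad ", 100))
  for (w in c(0, 10, 200, 500)) {
    m <- extract_pvalues(txt, window = w)
    expect_equal(nrow(m), 2L, info = paste("window", w))
    expect_true(all(nchar(m$context_before) <= w))
    expect_true(all(nchar(m$context_after) <= w))
  }
})

test_that("extraction is deterministic and order-preserving", {
  txt <- paste0("p=.01 ", strrep("f ", 50), "p=.02 ", strrep("f ", 50), "p=.03")
  m1 <- extract_pvalues(txt)
  m2 <- extract_pvalues(txt)
  expect_identical(m1, m2)
  expect_equal(m1$value, c(0.01, 0.02, 0.03))
  expect_true(all(diff(m1$offset) > 0))
})

test_that("range membership is exact on the printed decimal", {
  # boundary grid around .05 and .10 at several printed precisions
  grid <- c(".049999", ".05", "0.0500", ".050001", ".051", ".0999", ".1",
            ".10", "0.100000", ".100001", ".11", "5e-02", "6e-02", "1e-01")
  expected <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(value_in_range(grid), expected)
  expect_true(is.na(value_in_range(".")))
})
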