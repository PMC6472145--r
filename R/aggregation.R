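# Grouped summaries: the two outcome levels, confidence intervals, and
# per-article ratios.
#
# Outcome definitions (denominators matter):
#   * p-value level:  100 * n_marginal / n_inrange — the percentage of
#     p-values in (.05, .10] reported as marginally significant. Conditional
#     on range membership, so unaffected by the p-value distribution.
#   * article level:  100 * n_articles_marginal / n_articles_with_p — the
#     percentage of articles *containing p-values* with at least one in-range
#     p-value reported as marginally significant. The denominator is ALL
#     articles with p-values, not only those with in-range values.

#' Wald binomial confidence interval, on the percentage scale
#'
#' \code{100 * (p_hat +/- z * sqrt(p_hat (1 - p_hat) / n))}, clamped to
#' \code{[0, 100]}. Undefined (NA bounds) when \code{n} is 0 or missing.
#'
#' @param p_hat proportion(s) in \code{[0, 1]}.
#' @param n denominator count(s).
#' @param level confidence level (default 0.95).
#' @return data frame with columns \code{lower}, \code{upper} (percent).
#' @examples
#' wald_ci(0.3008, 10173)  # ~ [29.19, 30.97]
#' @export
wald_ci <- function(p_hat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  lower <- 100 * (p_hat - half)
  upper <- 100 * (p_hat + half)
  bad <- is.na(n) | n < 1
  lower[bad] <- NA_real_
  upper[bad] <- NA_real_
  data.frame(lower = pmax(0, lower), upper = pmin(100, upper))
}

#' Wilson score interval, on the percentage scale
#'
#' Alternative to [wald_ci()], selectable via \code{ci_method = "wilson"} in
#' [summarize_groups()]. Better behaved near 0 and 1.
#'
#' @inheritParams wald_ci
#' @return data frame with columns \code{lower}, \code{upper} (percent).
#' @export
wilson_ci <- function(p_hat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  lower <- 100 * (centre - half)
  upper <- 100 * (centre + half)
  bad <- is.na(n) | n < 1
  lower[bad] <- NA_real_
  upper[bad] <- NA_real_
  data.frame(lower = pmax(0, lower), upper = pmin(100, upper))
}

#' Per-article rollup
#'
#' Collapses labeled records to one row per article with the three nested
#' flags: contains any p-value, contains an in-range p-value, contains an
#' in-range p-value reported as marginal (\code{has_marginal} implies
#' \code{has_inrange} implies \code{has_p}).
#'
#' @param records labeled record data frame (needs \code{article_id},
#'   \code{in_range}, \code{is_marginal}).
#' @return data frame with columns \code{article_id}, \code{has_p},
#'   \code{has_inrange}, \code{has_marginal}.
#' @export
per_article_rollup <- function(records) {
  ids <- unique(records$article_id)
  inr <- records$in_range %in% TRUE
  marg <- inr & records$is_marginal %in% TRUE
  data.frame(
    article_id = ids,
    has_p = TRUE,
    has_inrange = ids %in% records$article_id[inr],
    has_marginal = ids %in% records$article_id[marg],
    stringsAsFactors = FALSE
  )
}

# Compute one GroupStats row from a set of record rows. `rows` must contain
# every p-value of the group that survived the metadata / numeric / core
# stages (in-range or not); in_range and is_marginal flags select the rest.
compute_group_stats <- function(rows, group, year = NA_integer_,
                                ci_method = c("wald", "wilson"),
                                level = 0.95) {
  ci_fun <- switch(match.arg(ci_method), wald = wald_ci, wilson = wilson_ci)
  inr <- rows$in_range %in% TRUE
  marg <- inr & rows$is_marginal %in% TRUE
  n_pvalues <- nrow(rows)
  n_articles <- length(unique(rows$article_id))
  n_inrange <- sum(inr)
  n_marginal <- sum(marg)
  n_articles_inrange <- length(unique(rows$article_id[inr]))
  n_articles_marginal <- length(unique(rows$article_id[marg]))
  pct_marginal <- if (n_inrange > 0) 100 * n_marginal / n_inrange else NA_real_
  pct_articles_marginal <- if (n_articles > 0) {
    100 * n_articles_marginal / n_articles
  } else {
    NA_real_
  }
  ci_pm <- if (n_inrange > 0) {
    ci_fun(n_marginal / n_inrange, n_inrange, level)
  } else {
    data.frame(lower = NA_real_, upper = NA_real_)
  }
  ci_pam <- if (n_articles > 0) {
    ci_fun(n_articles_marginal / n_articles, n_articles, level)
  } else {
    data.frame(lower = NA_real_, upper = NA_real_)
  }
  data.frame(
    group = group,
    year = year,
    n_journals = length(unique(rows$journal_canonical)),
    n_articles_with_p = n_articles,
    n_pvalues = n_pvalues,
    pvalues_per_article = if (n_articles > 0) n_pvalues / n_articles
                          else NA_real_,
    n_inrange = n_inrange,
    inrange_per_article = if (n_articles > 0) n_inrange / n_articles
                          else NA_real_,
    n_articles_with_inrange = n_articles_inrange,
    n_marginal = n_marginal,
    n_articles_marginal = n_articles_marginal,
    pct_marginal = pct_marginal,
    pct_marginal_lower = ci_pm$lower,
    pct_marginal_upper = ci_pm$upper,
    pct_articles_marginal = pct_articles_marginal,
    pct_articles_marginal_lower = ci_pam$lower,
    pct_articles_marginal_upper = ci_pam$upper,
    stringsAsFactors = FALSE
  )
}

#' Grouped summary statistics
#'
#' Computes one \code{GroupStats} row per group (and per year when
#' \code{per_year = TRUE}). Groupings:
#' \describe{
#'   \item{overall}{every row counted once.}
#'   \item{discipline}{multi-membership: a row is counted fully in every
#'     discipline its journal belongs to (its \code{disc_*} flags), so
#'     discipline counts can sum to more than the overall count.}
#'   \item{journal}{by canonical journal name.}
#' }
#' The input must contain every p-value that survived the metadata, numeric
#' and core-journal stages — including out-of-range ones, which feed the
#' article-level denominator and the per-article ratios. Rows excluded at
#' those earlier stages are ignored. With \code{per_year = TRUE}, rows with
#' unresolved year are excluded from yearly cells (and logged) but still
#' count in all-years cells.
#'
#' @param records labeled record data frame (see [classify_records()];
#'   needs \code{filter_status}, \code{in_range}, \code{is_marginal},
#'   \code{journal_canonical}, \code{year}, and \code{disc_*} flags for the
#'   discipline grouping).
#' @param by one of \code{"overall"}, \code{"discipline"}, \code{"journal"}.
#' @param per_year also emit one row per (group, year) cell.
#' @param ci_method \code{"wald"} (default) or \code{"wilson"}.
#' @param level confidence level.
#' @return data frame of \code{GroupStats} rows; all-years rows have
#'   \code{year = NA}.
#' @export
summarize_groups <- function(records,
                             by = c("overall", "discipline", "journal"),
                             per_year = FALSE,
                             ci_method = c("wald", "wilson"),
                             level = 0.95) {
  by <- match.arg(by)
  ci_method <- match.arg(ci_method)
  if ("filter_status" %in% names(records)) {
    keep <- records$filter_status %in% c("retained", "out_of_range")
    records <- records[keep, , drop = FALSE]
  }
  groups <- switch(by,
    overall = list(overall = seq_len(nrow(records))),
    journal = split(seq_len(nrow(records)), records$journal_canonical),
    discipline = {
      cols <- grep("^disc_", names(records), value = TRUE)
      if (!length(cols)) {
        stop("discipline grouping needs disc_* flag columns ",
             "(run assign_disciplines first)", call. = FALSE)
      }
      g <- lapply(cols, function(cc) which(records[[cc]]))
      names(g) <- sub("^disc_", "", cols)
      g
    })
  out <- lapply(names(groups), function(g) {
    rows <- records[groups[[g]], , drop = FALSE]
    res <- compute_group_stats(rows, g, NA_integer_, ci_method, level)
    if (per_year) {
      noyr <- sum(is.na(rows$year))
      if (noyr > 0) {
        message(noyr, " row(s) without year excluded from yearly cells",
                " in group '", g, "'")
      }
      yr_rows <- rows[!is.na(rows$year), , drop = FALSE]
      for (y in sort(unique(yr_rows$year))) {
        res <- rbind(res, compute_group_stats(
          yr_rows[yr_rows$year == y, , drop = FALSE], g, y, ci_method, level))
      }
    }
    res
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' GroupStats from summary counts
#'
#' Builds the derived quantities of one \code{GroupStats} row directly from
#' its integer counts — the per-article ratios, the two outcome percentages
#' and their confidence intervals — without record-level data. Useful for
#' checking published summary tables whose underlying corpus is unavailable.
#'
#' @param n_articles_with_p articles containing at least one p-value.
#' @param n_pvalues total extracted p-values.
#' @param n_inrange p-values in (.05, .10].
#' @param n_marginal in-range p-values reported as marginal.
#' @param n_articles_marginal articles with at least one marginal in-range
#'   p-value.
#' @param n_journals number of journals (optional bookkeeping).
#' @param group label.
#' @param ci_method,level see [summarize_groups()].
#' @return one-row \code{GroupStats} data frame.
#' @export
group_stats_from_counts <- function(n_articles_with_p, n_pvalues,
                                    n_inrange = NA_integer_,
                                    n_marginal = NA_integer_,
                                    n_articles_marginal = NA_integer_,
                                    n_journals = NA_integer_,
                                    group = "group",
                                    ci_method = c("wald", "wilson"),
                                    level = 0.95) {
  ci_fun <- switch(match.arg(ci_method), wald = wald_ci, wilson = wilson_ci)
  pct_marginal <- if (!is.na(n_marginal) && !is.na(n_inrange) && n_inrange > 0) {
    100 * n_marginal / n_inrange
  } else {
    NA_real_
  }
  pct_articles_marginal <- if (!is.na(n_articles_marginal) &&
                               n_articles_with_p > 0) {
    100 * n_articles_marginal / n_articles_with_p
  } else {
    NA_real_
  }
  ci_pm <- if (!is.na(pct_marginal)) {
    ci_fun(pct_marginal / 100, n_inrange, level)
  } else {
    data.frame(lower = NA_real_, upper = NA_real_)
  }
  ci_pam <- if (!is.na(pct_articles_marginal)) {
    ci_fun(pct_articles_marginal / 100, n_articles_with_p, level)
  } else {
    data.frame(lower = NA_real_, upper = NA_real_)
  }
  data.frame(
    group = group, year = NA_integer_, n_journals = n_journals,
    n_articles_with_p = n_articles_with_p, n_pvalues = n_pvalues,
    pvalues_per_article = n_pvalues / n_articles_with_p,
    n_inrange = n_inrange,
    inrange_per_article = n_inrange / n_articles_with_p,
    n_articles_with_inrange = NA_integer_,
    n_marginal = n_marginal, n_articles_marginal = n_articles_marginal,
    pct_marginal = pct_marginal,
    pct_marginal_lower = ci_pm$lower, pct_marginal_upper = ci_pm$upper,
    pct_articles_marginal = pct_articles_marginal,
    pct_articles_marginal_lower = ci_pam$lower,
    pct_articles_marginal_upper = ci_pam$upper,
    stringsAsFactors = FALSE
  )
}

#' Percentage of a total, at printed precision
#'
#' Tiny helper for percent-of-corpus bookkeeping: \code{100 * n / total},
#' optionally rounded half-up to a number of decimals.
#'
#' @param n,total counts.
#' @param digits decimals to round to (NULL for no rounding).
#' @return numeric percentage.
#' @export
pct_of_total <- function(n, total, digits = NULL) {
  p <- 100 * n / total
  if (!is.null(digits)) p <- round_half_up(p, digits)
  p
}

#' Half-up rounding
#'
#' Rounds half away from zero at \code{digits} decimals, as printed summary
#' tables conventionally do (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
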