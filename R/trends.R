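# Yearly percentage series and least-squares trend slopes.

#' Build a yearly percentage series
#'
#' Extracts (year, percentage) points for one group from a per-year summary
#' (see [summarize_groups()] with \code{per_year = TRUE}). Years whose
#' denominator is zero — an undefined percentage — are omitted, never
#' imputed as 0.
#'
#' @param stats \code{GroupStats} data frame with yearly rows.
#' @param outcome \code{"pvalue"} (percentage of in-range p-values reported
#'   as marginal) or \code{"article"} (percentage of articles with p-values
#'   having at least one marginal in-range p-value).
#' @param group group label to select (default: the first group present).
#' @return data frame with columns \code{group}, \code{year}, \code{pct}.
#' @export
yearly_series <- function(stats, outcome = c("pvalue", "article"),
                          group = NULL) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "pvalue") "pct_marginal" else "pct_articles_marginal"
  if (is.null(group)) group <- stats$group[1]
  sel <- stats$group == group & !is.na(stats$year) & !is.na(stats[[col]])
  pts <- stats[sel, c("group", "year", col)]
  names(pts)[3] <- "pct"
  pts[order(pts$year), , drop = FALSE]
}

#' Fit an unweighted least-squares trend
#'
#' Simple linear regression of percentage on calendar year,
#' \code{pct ~ year}, unweighted. The slope is in percentage points per
#' year; the intercept is also reported re-expressed at a readable origin
#' (default 1985, the first corpus year).
#'
#' @param points data frame with columns \code{year} and \code{pct}
#'   (as from [yearly_series()]).
#' @param origin year at which \code{intercept_at_origin} is evaluated.
#' @param weights optional per-year weights (default unweighted).
#' @return list of class \code{margex_trend}: \code{slope},
#'   \code{intercept}, \code{intercept_at_origin}, \code{se_slope},
#'   \code{n_years}, \code{points}.
#' @examples
#' fit_trend(data.frame(year = 1985:1987, pct = c(10, 11, 12)))$slope  # 1
#' @export
fit_trend <- function(points, origin = 1985L, weights = NULL) {
  if (nrow(points) < 2 || length(unique(points$year)) < 2) {
    stop("trend fit undefined: need at least 2 distinct years", call. = FALSE)
  }
  fit <- if (is.null(weights)) {
    lm(pct ~ year, data = points)
  } else {
    lm(pct ~ year, data = points, weights = weights)
  }
  cf <- coef(fit)
  # slope SE from the residuals directly (avoids the perfect-fit warning
  # summary.lm emits on exact lines)
  n <- nrow(points)
  sxx <- sum((points$year - mean(points$year))^2)
  sigma2 <- sum(residuals(fit)^2) / max(1, n - 2)
  se <- sqrt(sigma2 / sxx)
  structure(list(
    slope = unname(cf[["year"]]),
    intercept = unname(cf[["(Intercept)"]]),
    intercept_at_origin = unname(cf[["(Intercept)"]] + cf[["year"]] * origin),
    se_slope = se,
    n_years = nrow(points),
    points = points
  ), class = "margex_trend")
}

#' @export
print.margex_trend <- function(x, ...) {
  cat(sprintf(
    "Trend over %d years: slope %+0.3f pp/year (SE %0.3f), level %0.2f%% at origin\n",
    x$n_years, x$slope, x$se_slope, x$intercept_at_origin))
  invisible(x)
}

#' Trend slopes for every group and both outcomes
#'
#' Convenience wrapper: runs [yearly_series()] and [fit_trend()] for each
#' group in a per-year summary and both outcome levels, returning a tidy
#' table of slopes. Groups with fewer than 2 usable years are skipped.
#'
#' @param stats per-year \code{GroupStats} data frame.
#' @param origin see [fit_trend()].
#' @return data frame with columns \code{group}, \code{outcome},
#'   \code{slope}, \code{se_slope}, \code{n_years}.
#' @export
trend_table <- function(stats, origin = 1985L) {
  out <- list()
  for (g in unique(stats$group)) {
    for (oc in c("pvalue", "article")) {
      pts <- yearly_series(stats, oc, group = g)
      if (nrow(pts) < 2 || length(unique(pts$year)) < 2) next
      f <- fit_trend(pts, origin = origin)
      out[[length(out) + 1]] <- data.frame(
        group = g, outcome = oc, slope = f$slope, se_slope = f$se_slope,
        n_years = f$n_years, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
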