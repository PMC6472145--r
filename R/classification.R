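# Context-window stem search for "reported as marginally significant".

stem_pattern <- function(stems) {
  # word-initial: preceded by start-of-context or a non-letter; the stem may
  # continue with any letters ("marginally", "margins", "approached", ...)
  paste0("(?<![[:alpha:]])(", paste(stems, collapse = "|"), ")[[:alpha:]]*")
}

#' Classify one p-value mention as reported-as-marginal
#'
#' Searches the captured context windows (and nothing else) for word-initial
#' occurrences of the given stems. A p-value is "reported as marginally
#' significant" iff at least one stem matches in either window. The search is
#' case-insensitive by default and is a pure function of the two context
#' strings; mentions are classified independently even when their windows
#' overlap in the source document.
#'
#' Note the method's known false positives: any word starting with a stem
#' counts ("profit margins" as much as "marginally significant").
#'
#' @param context_before,context_after the captured windows (each at most
#'   the extraction window, 200 characters by default).
#' @param stems character vector of word-initial stems.
#' @param ignore_case case-insensitive matching (default TRUE).
#' @return list with \code{is_marginal} (logical) and \code{matches}, a data
#'   frame with one row per stem hit: \code{stem}, \code{matched_text},
#'   \code{where} ("before"/"after") and 0-based \code{offset} within that
#'   window.
#' @examples
#' classify_marginal("the interaction approached significance: ", "")
#' @export
classify_marginal <- function(context_before, context_after,
                              stems = c("margin", "approach"),
                              ignore_case = TRUE) {
  pat <- stem_pattern(stems)
  if (ignore_case) pat <- paste0("(?i)", pat)
  hit <- function(ctx, where) {
    if (is.na(ctx) || !nzchar(ctx)) {
      return(NULL)
    }
    m <- gregexpr(pat, ctx, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start <- as.integer(m)
    len <- attr(m, "match.length")
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    data.frame(
      stem = tolower(substring(ctx, cs[, 1], cs[, 1] + cl[, 1] - 1L)),
      matched_text = substring(ctx, start, start + len - 1L),
      where = where,
      offset = start - 1L,
      stringsAsFactors = FALSE
    )
  }
  matches <- rbind(hit(context_before, "before"), hit(context_after, "after"))
  if (is.null(matches)) {
    matches <- data.frame(stem = character(0), matched_text = character(0),
                          where = character(0), offset = integer(0),
                          stringsAsFactors = FALSE)
  }
  list(is_marginal = nrow(matches) > 0, matches = matches)
}

#' Classify all retained records
#'
#' Vectorised wrapper around the window stem search: adds \code{is_marginal}
#' and \code{n_stem_matches} columns. Rows whose \code{filter_status} is not
#' \code{"retained"} (when that column exists) get \code{NA}, since the
#' outcome is only defined for p-values in (.05, .10].
#'
#' @param records record data frame with \code{context_before} /
#'   \code{context_after}.
#' @param stems,ignore_case see [classify_marginal()].
#' @return \code{records} with the label columns added.
#' @export
classify_records <- function(records, stems = c("margin", "approach"),
                             ignore_case = TRUE) {
  pat <- stem_pattern(stems)
  if (ignore_case) pat <- paste0("(?i)", pat)
  ctx_b <- ifelse(is.na(records$context_before), "", records$context_before)
  ctx_a <- ifelse(is.na(records$context_after), "", records$context_after)
  found <- grepl(pat, ctx_b, perl = TRUE) | grepl(pat, ctx_a, perl = TRUE)
  nmatch <- integer(length(found))
  count_hits <- function(ctx) {
    vapply(gregexpr(pat, ctx, perl = TRUE),
           function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  }
  if (any(found)) {
    nmatch[found] <- count_hits(ctx_b[found]) + count_hits(ctx_a[found])
  }
  records$is_marginal <- found
  records$n_stem_matches <- nmatch
  if ("filter_status" %in% names(records)) {
    off <- records$filter_status != "retained"
    records$is_marginal[off] <- NA
    records$n_stem_matches[off] <- NA_integer_
  }
  records
}
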