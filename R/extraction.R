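# Regular-expression grammar for reported p-values and context capture.

#' Build the p-value matching pattern
#'
#' Constructs the PCRE pattern for one reported p-value: a standalone
#' \code{p}/\code{P} token (not adjacent to a letter or digit), optional
#' whitespace or markup remnants (\code{*}, \code{_} left over from
#' HTML-to-text conversion), a comparison sign, and a numeric value
#' (\code{.05}, \code{0.05}, \code{1.2}, \code{6e-05}; a bare \code{.} also
#' matches so that broken numbers are surfaced to the non-numeric filter
#' rather than silently dropped).
#'
#' @param match_plural_ps also match the plural token \code{ps} (e.g.
#'   "all ps > .30"). Off by default.
#' @param extended_signs accept \code{<=}, \code{>=}, \code{=<}, \code{=>}
#'   and the Unicode signs, normalised to \code{<=} / \code{>=}. When
#'   \code{FALSE} only \code{<}, \code{>}, \code{=} are matched.
#' @return a single PCRE pattern string with capture groups
#'   (sign, value).
#' @keywords internal
pvalue_pattern <- function(match_plural_ps = FALSE, extended_signs = TRUE) {
  token <- if (match_plural_ps) "[pP][sS]?" else "[pP]"
  sign <- if (extended_signs) {
    "(<=|>=|=<|=>|≤|≥|<|>|=)"
  } else {
    "([<>=])"
  }
  num <- "((?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]*)(?:[eE][-+]?[0-9]+)?)"
  paste0("(?<![[:alnum:]])", token, "[\\s*_]*", sign, "[\\s*_]*", num)
}

#' Normalise a comparison sign
#'
#' Maps the matched sign variants onto the five canonical comparisons
#' \code{<}, \code{>}, \code{=}, \code{<=}, \code{>=} (the last two stand for
#' the Unicode less/greater-or-equal signs).
#'
#' @param sign character vector of matched signs.
#' @return character vector of canonical signs.
#' @keywords internal
normalize_sign <- function(sign) {
  out <- sign
  out[sign %in% c("=<", "<=", "≤")] <- "<="
  out[sign %in% c("=>", ">=", "≥")] <- ">="
  out
}

#' Parse a printed p-value
#'
#' Parses the numeric substring of a p-value report exactly as printed.
#' Accepted forms are \code{.05}, \code{0.05}, \code{1.2}, \code{6e-05};
#' anything else (e.g. a bare \code{.}) yields \code{NA}, the invalid
#' marker counted by the non-numeric filter. Values above 1 (misreports such
#' as \code{1.2}) parse as printed and are left for the range filter.
#'
#' @param value_text character vector of printed numeric substrings.
#' @return numeric vector; \code{NA} where the text is not a number.
#' @examples
#' parse_value(c(".048", "0.05", "1.2", ".", "6e-05"))
#' @export
parse_value <- function(value_text) {
  ok <- grepl("^(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][-+]?[0-9]+)?$",
              value_text) & grepl("[0-9]", value_text)
  out <- rep(NA_real_, length(value_text))
  out[ok] <- as.numeric(value_text[ok])
  out
}

#' Extract reported p-values with bounded context
#'
#' Scans an article body for p-value reports and returns one row per
#' non-overlapping match, in document order, with the verbatim matched text,
#' the normalised comparison sign, the printed and parsed value, the 0-based
#' character offset of the match, and up to \code{window} characters of
#' context on each side (truncated, never padded, at document boundaries).
#' Windows are counted in characters, not bytes.
#'
#' @param text article body (single string) or a corpus data frame as
#'   returned by [read_corpus()] (columns \code{article_id}, \code{text},
#'   and optionally \code{doi}, \code{journal_raw}, \code{year}, which are
#'   carried through).
#' @param article_id id attached to the mentions when \code{text} is a
#'   plain string.
#' @param window context width in characters on each side (default 200).
#' @param match_plural_ps,extended_signs see [pvalue_pattern()].
#' @return data frame with columns \code{article_id}, \code{raw},
#'   \code{comparison}, \code{value_text}, \code{value}, \code{offset},
#'   \code{context_before}, \code{context_after} (plus any carried metadata
#'   columns).
#' @examples
#' extract_pvalues("the effect was marginal, p = .06, in study 2")
#' @export
extract_pvalues <- function(text, article_id = "doc1", window = 200,
                            match_plural_ps = FALSE, extended_signs = TRUE) {
  if (is.data.frame(text)) {
    docs <- text
    stopifnot(all(c("article_id", "text") %in% names(docs)))
    res <- lapply(seq_len(nrow(docs)), function(i) {
      extract_pvalues(docs$text[i], docs$article_id[i], window = window,
                      match_plural_ps = match_plural_ps,
                      extended_signs = extended_signs)
    })
    out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    if (is.null(out)) out <- empty_mentions()
    meta <- intersect(c("doi", "journal_raw", "year"), names(docs))
    if (length(meta) && nrow(out)) {
      idx <- match(out$article_id, docs$article_id)
      for (m in meta) out[[m]] <- docs[[m]][idx]
    } else if (length(meta)) {
      for (m in meta) out[[m]] <- docs[[m]][0]
    }
    return(out)
  }
  stopifnot(is.character(text), length(text) == 1, window >= 0)
  if (is.na(text) || !nzchar(text)) return(empty_mentions(article_id))
  text <- enc2utf8(text)
  pat <- pvalue_pattern(match_plural_ps, extended_signs)
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_mentions(article_id))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  raw <- substring(text, start, start + len - 1L)
  sign <- substring(text, cs[, 1], cs[, 1] + cl[, 1] - 1L)
  value_text <- substring(text, cs[, 2], cs[, 2] + cl[, 2] - 1L)
  ctx_before <- substring(text, pmax(1L, start - window), start - 1L)
  end <- start + len - 1L
  ctx_after <- substring(text, end + 1L, end + window)
  data.frame(
    article_id = article_id,
    raw = raw,
    comparison = normalize_sign(sign),
    value_text = value_text,
    value = parse_value(value_text),
    offset = start - 1L,
    context_before = ctx_before,
    context_after = ctx_after,
    stringsAsFactors = FALSE
  )
}

empty_mentions <- function(article_id = character(0)) {
  data.frame(
    article_id = character(0), raw = character(0), comparison = character(0),
    value_text = character(0), value = numeric(0), offset = integer(0),
    context_before = character(0), context_after = character(0),
    stringsAsFactors = FALSE
  )
}

# ---- exact decimal comparison -------------------------------------------

# Compare two printed decimal numbers (optionally with exponent) exactly,
# by aligning digit strings instead of going through binary doubles, so the
# .05 / .10 range boundaries are exact for any printed precision.
# Returns -1, 0, 1, or NA when either side is not a valid number.
dec_cmp <- function(a, b) {
  pa <- dec_parse(a)
  pb <- dec_parse(b)
  mapply(function(x, y) {
    if (is.null(x) || is.null(y)) return(NA_integer_)
    # value = digits * 10^exp; align exponents by right-padding with zeros
    shift <- x$exp - y$exp
    dx <- x$digits
    dy <- y$digits
    if (shift > 0) dx <- paste0(dx, strrep("0", shift))
    if (shift < 0) dy <- paste0(dy, strrep("0", -shift))
    w <- max(nchar(dx), nchar(dy))
    dx <- paste0(strrep("0", w - nchar(dx)), dx)
    dy <- paste0(strrep("0", w - nchar(dy)), dy)
    if (dx < dy) -1L else if (dx > dy) 1L else 0L
  }, pa, pb)
}

dec_parse <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) ||
        !grepl("^(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][-+]?[0-9]+)?$", v) ||
        !grepl("[0-9]", v)) {
      return(NULL)
    }
    ex <- 0L
    if (grepl("[eE]", v)) {
      parts <- strsplit(v, "[eE]")[[1]]
      v <- parts[1]
      ex <- as.integer(parts[2])
    }
    if (grepl("\\.", v)) {
      parts <- strsplit(v, "\\.", fixed = FALSE)[[1]]
      int <- if (length(parts) >= 1) parts[1] else ""
      frac <- if (length(parts) >= 2) parts[2] else ""
      digits <- paste0(int, frac)
      ex <- ex - nchar(frac)
    } else {
      digits <- v
    }
    if (!nzchar(digits)) digits <- "0"
    list(digits = digits, exp = ex)
  })
}

#' Exact range test for printed p-values
#'
#' Tests \code{lower < value <= upper} on the printed decimal representation
#' (exact digit-string comparison, no binary floating point), so the default
#' boundaries .05 (excluded) and .10 (included) are decided exactly whatever
#' the printed precision. The comparison ignores the reported sign: a value
#' of exactly .05 is out of range whether reported with <, > or =.
#'
#' @param value_text character vector of printed values.
#' @param lower,upper boundary values as strings.
#' @return logical vector; \code{NA} for non-numeric text.
#' @examples
#' value_in_range(c(".05", ".050001", ".10", ".1000001", "."))
#' @export
value_in_range <- function(value_text, lower = "0.05", upper = "0.10") {
  dec_cmp(value_text, lower) > 0L & dec_cmp(value_text, upper) <= 0L
}
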