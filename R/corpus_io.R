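# Corpus and record-level dataset input/output.
#
# Two corpus layouts are supported: a directory of UTF-8 .txt files (one
# article each) with a metadata.csv sidecar, or a line-delimited JSON file
# with one {article_id, doi, journal, year, text} object per line. The
# record-level dataset (one row per extracted p-value) round-trips through
# CSV (interoperable; the literal string "NA" in free text is not
# distinguishable from a missing value) or JSON lines (lossless).

RECORD_SCHEMA_VERSION <- "1"

# Fixed leading columns of a record row; any extra "disc_*" columns are
# per-discipline logical flags and are preserved as such.
record_schema <- function() {
  c(article_id = "character", doi = "character", journal_raw = "character",
    journal_canonical = "character", year = "integer", raw = "character",
    comparison = "character", value_text = "character", value = "numeric",
    offset = "integer", context_before = "character",
    context_after = "character", in_range = "logical",
    is_marginal = "logical", filter_status = "character")
}

#' Read an article corpus
#'
#' Reads either a directory of UTF-8 \code{.txt} files (the file stem is the
#' article id) with an optional \code{metadata.csv} sidecar (columns
#' \code{article_id}, \code{doi}, \code{journal}, \code{year}), or a
#' \code{.jsonl} file with one JSON object per line. Missing metadata fields
#' are preserved as \code{NA}, never coerced to empty strings. Bytes that are
#' not valid UTF-8 are replaced, not fatal.
#'
#' @param path directory or \code{.jsonl} file.
#' @return data frame with columns \code{article_id}, \code{doi},
#'   \code{journal_raw}, \code{year}, \code{text}; one row per article.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    stop("corpus path does not exist: ", path, call. = FALSE)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    ids <- sub("\\.txt$", "", basename(files))
    text <- vapply(files, function(f) {
      raw <- readBin(f, "raw", file.info(f)$size)
      s <- rawToChar(raw)
      Encoding(s) <- "UTF-8"
      if (!validUTF8(s)) s <- iconv(s, "UTF-8", "UTF-8", sub = "�")
      s
    }, character(1), USE.NAMES = FALSE)
    docs <- data.frame(article_id = ids,
                       doi = rep(NA_character_, length(ids)),
                       journal_raw = rep(NA_character_, length(ids)),
                       year = rep(NA_integer_, length(ids)),
                       text = text, stringsAsFactors = FALSE)
    meta_path <- file.path(path, "metadata.csv")
    if (file.exists(meta_path)) {
      meta <- read.csv(meta_path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"),
                       colClasses = c(article_id = "character",
                                      doi = "character",
                                      journal = "character",
                                      year = "integer"))
      idx <- match(docs$article_id, meta$article_id)
      docs$doi <- meta$doi[idx]
      docs$journal_raw <- meta$journal[idx]
      docs$year <- meta$year[idx]
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop("malformed corpus line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      data.frame(
        article_id = as.character(obj$article_id),
        doi = if (is.null(obj$doi)) NA_character_ else as.character(obj$doi),
        journal_raw = if (is.null(obj$journal)) NA_character_
                      else as.character(obj$journal),
        year = if (is.null(obj$year)) NA_integer_ else as.integer(obj$year),
        text = if (is.null(obj$text)) "" else as.character(obj$text),
        stringsAsFactors = FALSE
      )
    })
    docs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(docs)) {
      docs <- data.frame(article_id = character(0), doi = character(0),
                         journal_raw = character(0), year = integer(0),
                         text = character(0), stringsAsFactors = FALSE)
    }
  }
  if (anyDuplicated(docs$article_id)) {
    stop("duplicate article_id in corpus: ",
         docs$article_id[duplicated(docs$article_id)][1], call. = FALSE)
  }
  docs
}

#' Write an article corpus
#'
#' Inverse of [read_corpus()]: writes a directory of \code{.txt} files plus
#' \code{metadata.csv}, or a \code{.jsonl} file, depending on whether
#' \code{path} ends in \code{.jsonl}.
#'
#' @param docs corpus data frame as returned by [read_corpus()] or
#'   [generate_corpus()].
#' @param path output directory or \code{.jsonl} file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(docs, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(docs))) {
      obj <- list(article_id = docs$article_id[i], doi = docs$doi[i],
                  journal = docs$journal_raw[i], year = docs$year[i],
                  text = docs$text[i])
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(docs))) {
      writeLines(docs$text[i],
                 file.path(path, paste0(docs$article_id[i], ".txt")),
                 useBytes = TRUE)
    }
    meta <- data.frame(article_id = docs$article_id, doi = docs$doi,
                       journal = docs$journal_raw, year = docs$year)
    write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Validate record rows
#'
#' Checks the record-row invariants: required columns present, context
#' windows at most 200 characters, and comparison signs canonical. Errors
#' name the offending field.
#'
#' @param records record data frame.
#' @param window maximum context width.
#' @return \code{records}, invisibly.
#' @export
validate_records <- function(records, window = 200) {
  need <- c("article_id", "raw", "comparison", "value_text", "value",
            "offset", "context_before", "context_after")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(nchar(records$context_before, type = "chars") > window)) {
    stop("invalid field context_before: exceeds ", window, " characters",
         call. = FALSE)
  }
  if (any(nchar(records$context_after, type = "chars") > window)) {
    stop("invalid field context_after: exceeds ", window, " characters",
         call. = FALSE)
  }
  ok_sign <- records$comparison %in% c("<", ">", "=", "<=", ">=")
  if (!all(ok_sign)) {
    stop("invalid field comparison: ",
         records$comparison[!ok_sign][1], call. = FALSE)
  }
  invisible(records)
}

#' Write / read the record-level p-value dataset
#'
#' One row per extracted p-value. \code{.csv} output is fully quoted CSV
#' with empty fields for missing values (interoperable, near-lossless);
#' \code{.jsonl} writes one JSON object per row with native \code{null} for
#' missing values and is the lossless route. The schema version is recorded
#' in a header comment (JSONL) or implied by the column set (CSV).
#'
#' @param records record data frame (validated against the row invariants).
#' @param path output file ending in \code{.csv} or \code{.jsonl}.
#' @return \code{path} invisibly (write) or the record data frame (read).
#' @export
write_records <- function(records, path) {
  validate_records(records)
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- as.list(records[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
  } else {
    write.csv(records, path, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  sch <- record_schema()
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed record line ", i,
                                               call. = FALSE))
      obj[vapply(obj, is.null, logical(1))] <- NA
      as.data.frame(obj, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    first <- readLines(path, n = 1, encoding = "UTF-8")
    cols <- strsplit(gsub('"', "", first), ",")[[1]]
    classes <- ifelse(cols %in% names(sch), sch[cols],
                      ifelse(startsWith(cols, "disc_"), "logical", NA))
    out <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = unname(classes), fileEncoding = "UTF-8")
  }
  # enforce schema types present in the file
  for (nm in intersect(names(sch), names(out))) {
    out[[nm]] <- switch(sch[[nm]],
                        character = as.character(out[[nm]]),
                        integer = as.integer(out[[nm]]),
                        numeric = as.numeric(out[[nm]]),
                        logical = as.logical(out[[nm]]))
  }
  for (nm in grep("^disc_", names(out), value = TRUE)) {
    out[[nm]] <- as.logical(out[[nm]])
  }
  out
}
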