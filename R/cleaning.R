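# Filter cascade, journal standardisation, metadata completion, discipline
# assignment and the stratified test sample.

#' Read a journal registry
#'
#' The registry maps raw journal names (including historical names) to their
#' current canonical name, a set of discipline identifiers, and a
#' core-of-psychology flag. Lookup is case- and whitespace-insensitive.
#' File format: CSV with columns \code{raw_name}, \code{canonical_name},
#' \code{disciplines} (semicolon-separated identifiers) and \code{core_only}
#' (TRUE/FALSE).
#'
#' @param path CSV file, or a data frame with the same columns.
#' @return object of class \code{journal_registry}.
#' @export
read_journal_registry <- function(path) {
  reg <- if (is.data.frame(path)) {
    path
  } else {
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(raw_name = "character",
                            canonical_name = "character",
                            disciplines = "character",
                            core_only = "logical"))
  }
  need <- c("raw_name", "canonical_name", "disciplines", "core_only")
  miss <- setdiff(need, names(reg))
  if (length(miss)) {
    stop("registry missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  reg$core_only[is.na(reg$core_only)] <- FALSE
  bad <- !reg$core_only & !nzchar(trimws(reg$disciplines))
  if (any(bad)) {
    stop("registry entry without disciplines and not core_only: ",
         reg$raw_name[bad][1], call. = FALSE)
  }
  reg$key <- journal_key(reg$raw_name)
  if (anyDuplicated(reg$key)) {
    stop("duplicate raw_name in registry: ",
         reg$raw_name[duplicated(reg$key)][1], call. = FALSE)
  }
  structure(reg, class = c("journal_registry", "data.frame"))
}

journal_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' All discipline identifiers in a registry
#' @param registry a \code{journal_registry}.
#' @return sorted character vector of discipline ids.
#' @export
registry_disciplines <- function(registry) {
  sort(unique(unlist(strsplit(registry$disciplines, ";", fixed = TRUE))))
}

#' Standardise journal names
#'
#' Maps raw (possibly historical) journal names to their canonical names.
#' Unknown names are returned unchanged, with one warning summarising them;
#' canonical names map to themselves (idempotent).
#'
#' @param name character vector of raw journal names.
#' @param registry a \code{journal_registry}.
#' @return character vector of canonical names.
#' @export
standardize_journal <- function(name, registry) {
  idx <- match(journal_key(name), registry$key)
  out <- ifelse(is.na(idx), name, registry$canonical_name[idx])
  unknown <- unique(name[is.na(idx) & !is.na(name)])
  if (length(unknown)) {
    warning("journal name(s) not in registry, left unchanged: ",
            paste(head(unknown, 5), collapse = "; "),
            if (length(unknown) > 5) " ..." else "", call. = FALSE)
  }
  out
}

#' Fill missing metadata through an injectable resolver
#'
#' For every record with a DOI and a missing journal or year, calls
#' \code{resolver(doi)}, which must return \code{list(journal =, year =)}
#' (either element may be \code{NULL}). Only missing fields are overwritten;
#' rows without a DOI are untouched; a resolver failure leaves the row
#' incomplete and is logged, never fatal.
#'
#' @param records record data frame with columns \code{doi},
#'   \code{journal_raw}, \code{year}.
#' @param resolver function of one DOI; a lookup table for tests, a network
#'   client in production.
#' @return list with elements \code{records} and \code{n_resolved}.
#' @export
complete_metadata <- function(records, resolver) {
  needs <- !is.na(records$doi) &
    (is.na(records$journal_raw) | is.na(records$year))
  n_resolved <- 0L
  for (doi in unique(records$doi[needs])) {
    res <- tryCatch(resolver(doi), error = function(e) {
      message("metadata resolution failed for ", doi, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows <- which(needs & records$doi == doi)
    if (!is.null(res$journal)) {
      fill <- rows[is.na(records$journal_raw[rows])]
      records$journal_raw[fill] <- res$journal
    }
    if (!is.null(res$year)) {
      fill <- rows[is.na(records$year[rows])]
      records$year[fill] <- as.integer(res$year)
    }
    n_resolved <- n_resolved + length(rows)
  }
  list(records = records, n_resolved = n_resolved)
}

#' Apply the filter cascade
#'
#' Stamps every record with the first filter stage that excludes it, in this
#' order: (1) \code{missing_metadata} — DOI, journal and year all missing;
#' (2) \code{nonnumeric} — the printed value did not parse; (3)
#' \code{core_excluded} — the journal is unique to the core-of-psychology
#' topic (\code{core_only} in the registry); (4) \code{out_of_range} — the
#' value is not in (.05, .10], decided on the exact printed decimal and
#' regardless of the comparison sign; otherwise \code{retained}. The stages
#' are mutually exclusive, so the report counts sum to the input count.
#'
#' @param records record data frame; journal names should be standardised
#'   first (a \code{journal_canonical} column is used when present, else
#'   \code{journal_raw}).
#' @param registry a \code{journal_registry} (used for the core-only stage).
#' @return list with \code{records} (all rows, with \code{filter_status} and
#'   \code{in_range} columns), \code{retained} (the in-range subset) and
#'   \code{report} (named counts and percentages, see Details).
#' @export
apply_filters <- function(records, registry) {
  n <- nrow(records)
  journal <- if ("journal_canonical" %in% names(records)) {
    records$journal_canonical
  } else {
    records$journal_raw
  }
  status <- rep("retained", n)
  in_range <- value_in_range(records$value_text)
  in_range[is.na(in_range)] <- FALSE

  missing_meta <- is.na(records$doi) & is.na(journal) & is.na(records$year)
  nonnumeric <- is.na(records$value)
  core_idx <- match(journal_key(journal), registry$key)
  core <- !is.na(core_idx) & registry$core_only[core_idx]

  status[!in_range] <- "out_of_range"
  status[core] <- "core_excluded"
  status[nonnumeric] <- "nonnumeric"
  status[missing_meta] <- "missing_metadata"

  records$filter_status <- status
  records$in_range <- in_range & status == "retained"
  report <- filter_report(status)
  list(records = records,
       retained = records[records$filter_status == "retained", , drop = FALSE],
       report = report)
}

filter_report <- function(status) {
  n <- length(status)
  counts <- c(
    n_input = n,
    n_missing_metadata = sum(status == "missing_metadata"),
    n_nonnumeric = sum(status == "nonnumeric"),
    n_core_excluded = sum(status == "core_excluded"),
    n_out_of_range = sum(status == "out_of_range"),
    n_retained = sum(status == "retained")
  )
  pct <- if (n > 0) 100 * counts[-1] / n else counts[-1] * NA_real_
  names(pct) <- sub("^n_", "pct_", names(counts)[-1])
  c(as.list(counts), as.list(pct))
}

#' Assign discipline membership flags
#'
#' Adds one logical column per discipline id (prefixed \code{disc_}). A
#' journal may belong to several disciplines, so several flags can be true
#' for one row; core-of-psychology is not a discipline. Unknown journals get
#' all flags false, with a warning.
#'
#' @param records record data frame with standardised journal names in
#'   \code{journal_canonical}.
#' @param registry a \code{journal_registry}.
#' @return \code{records} with \code{disc_*} columns appended.
#' @export
assign_disciplines <- function(records, registry) {
  discs <- registry_disciplines(registry)
  idx <- match(journal_key(records$journal_canonical), registry$key)
  unknown <- unique(records$journal_canonical[is.na(idx) &
                                                !is.na(records$journal_canonical)])
  if (length(unknown)) {
    warning("journal(s) not in registry, all discipline flags false: ",
            paste(head(unknown, 5), collapse = "; "), call. = FALSE)
  }
  memb <- strsplit(registry$disciplines, ";", fixed = TRUE)
  known <- !is.na(idx)
  for (d in discs) {
    has <- vapply(memb, function(m) d %in% m, logical(1))
    flag <- rep(FALSE, nrow(records))
    flag[known] <- has[idx[known]]
    records[[paste0("disc_", d)]] <- flag
  }
  records
}

#' Stratified random sample of records
#'
#' Draws, within each stratum (by default the canonical journal),
#' \code{round_half_up(fraction * n)} rows without replacement. Reproducible
#' for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param records record data frame.
#' @param fraction sampling fraction in (0, 1].
#' @param stratum name of the stratification column.
#' @param seed integer seed.
#' @return the sampled rows.
#' @export
stratified_sample <- function(records, fraction = 0.06,
                              stratum = "journal_canonical", seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  groups <- split(seq_len(nrow(records)), records[[stratum]])
  take <- unlist(lapply(groups, function(ix) {
    k <- floor(fraction * length(ix) + 0.5)  # half-up
    if (k == 0) integer(0) else sample(ix, k)
  }), use.names = FALSE)
  records[sort(take), , drop = FALSE]
}
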