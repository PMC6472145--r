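# One-call pipeline: extract -> clean -> classify -> aggregate -> trend,
# with a manifest and a resolved-config copy written next to the outputs.

default_config <- function() {
  list(
    corpus = NULL,          # path to a corpus (dir or .jsonl), or NULL
    simulate = NULL,        # sim_config(), or a list of its arguments
    registry = NULL,        # registry path/data frame; NULL -> sim registry
    out_dir = NULL,         # where outputs go; NULL -> nothing written
    window = 200L,
    stems = c("margin", "approach"),
    match_plural_ps = FALSE,
    extended_signs = TRUE,
    ignore_case = TRUE,
    ci_method = "wald",
    by = c("overall", "discipline"),
    per_year = TRUE,
    sample_fraction = NULL, # e.g. 0.06 for a stratified test sample
    resolver = NULL,        # doi -> list(journal =, year =); NULL to skip
    seed = 1L
  )
}

#' Run the full pipeline
#'
#' Chains every stage under one configuration: read (or simulate) the
#' corpus, extract p-value mentions, standardise journals, complete missing
#' metadata through the injectable resolver, assign disciplines, apply the
#' filter cascade, classify retained mentions, summarise per grouping (and
#' per year), and fit trend slopes. All randomness flows from
#' \code{config$seed}. Unknown configuration keys are rejected.
#'
#' When \code{out_dir} is set, the stage outputs are written there:
#' \code{records.csv}, \code{stats_<by>.csv}, \code{trends.csv},
#' \code{sample.csv} (if a sample fraction is configured),
#' \code{manifest.json} (stage counts, mirroring the filter report) and
#' \code{config.json} (the resolved configuration).
#'
#' @param config named list overriding the defaults (see Details), or a
#'   path to a JSON file with the same keys.
#' @return list with \code{records}, \code{report}, \code{stats} (one data
#'   frame per grouping), \code{trends}, \code{sample}, \code{truth} (for
#'   simulated corpora) and \code{manifest}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!inherits(sim, "sim_config")) {
      sim$seed <- sim$seed %||% cfg$seed
      sim <- do.call(sim_config, sim)
    }
    gen <- generate_corpus(sim)
    docs <- gen$articles
    truth <- gen$truth
    if (is.null(cfg$registry)) cfg$registry <- sim_registry(sim)
    if (is.null(cfg$resolver)) cfg$resolver <- sim_resolver(docs)
  } else if (!is.null(cfg$corpus)) {
    docs <- read_corpus(cfg$corpus)
  } else {
    stop("config needs either 'corpus' or 'simulate'", call. = FALSE)
  }
  registry <- if (inherits(cfg$registry, "journal_registry")) {
    cfg$registry
  } else if (!is.null(cfg$registry)) {
    read_journal_registry(cfg$registry)
  } else {
    stop("config needs a journal registry", call. = FALSE)
  }

  records <- extract_pvalues(docs, window = cfg$window,
                             match_plural_ps = cfg$match_plural_ps,
                             extended_signs = cfg$extended_signs)
  n_resolved <- 0L
  if (!is.null(cfg$resolver)) {
    res <- complete_metadata(records, cfg$resolver)
    records <- res$records
    n_resolved <- res$n_resolved
  }
  records$journal_canonical <- suppressWarnings(
    standardize_journal(records$journal_raw, registry))
  records <- suppressWarnings(assign_disciplines(records, registry))
  flt <- apply_filters(records, registry)
  records <- classify_records(flt$records, stems = cfg$stems,
                              ignore_case = cfg$ignore_case)

  stats <- lapply(cfg$by, function(b) {
    suppressMessages(summarize_groups(records, by = b,
                                      per_year = cfg$per_year,
                                      ci_method = cfg$ci_method))
  })
  names(stats) <- cfg$by
  trends <- if (cfg$per_year) {
    do.call(rbind, c(lapply(stats, trend_table),
                     list(make.row.names = FALSE)))
  }
  smp <- if (!is.null(cfg$sample_fraction)) {
    stratified_sample(records[records$filter_status == "retained", ,
                              drop = FALSE],
                      fraction = cfg$sample_fraction, seed = cfg$seed)
  }
  manifest <- c(list(schema_version = RECORD_SCHEMA_VERSION,
                     n_articles = nrow(docs),
                     n_resolved_metadata = n_resolved),
                flt$report)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_records(records, file.path(cfg$out_dir, "records.csv"))
    for (b in names(stats)) {
      write.csv(stats[[b]], file.path(cfg$out_dir,
                                      paste0("stats_", b, ".csv")),
                row.names = FALSE, na = "NA")
    }
    if (!is.null(trends)) {
      write.csv(trends, file.path(cfg$out_dir, "trends.csv"),
                row.names = FALSE, na = "NA")
    }
    if (!is.null(smp)) {
      write_records(smp, file.path(cfg$out_dir, "sample.csv"))
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    keep <- !vapply(cfg, is.function, logical(1)) &
      !names(cfg) %in% c("registry", "simulate")
    jsonlite::write_json(cfg[keep], file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(records = records, report = flt$report, stats = stats,
       trends = trends, sample = smp, truth = truth, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
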