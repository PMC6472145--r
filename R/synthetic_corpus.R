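# Synthetic article corpus with per-mention ground truth.
#
# The generator writes filler prose (guaranteed free of the classifier
# stems) interleaved with p-value sentences. Every generated report is
# recorded in a ground-truth table with its exact character offset, printed
# value, and whether a stem-bearing phrase was placed inside its 200-character
# window (intended marginal) or a decoy outside it. Consecutive reports are
# separated by at least 450 filler characters so context windows of distinct
# mentions never capture each other's phrases: label agreement on a clean
# configuration is exactly 1.

# filler word bank: no word contains the stems "margin" or "approach", no
# standalone "p" token, no digits, no comparison signs.
FILLER_BANK <- c(
  "the", "study", "design", "included", "several", "conditions", "and",
  "participants", "completed", "tasks", "in", "a", "fixed", "order",
  "responses", "were", "recorded", "by", "trained", "assistants", "data",
  "were", "screened", "for", "outliers", "before", "analysis", "results",
  "of", "this", "experiment", "are", "summarised", "below", "we", "note",
  "that", "each", "session", "lasted", "about", "one", "hour", "stimuli",
  "were", "presented", "on", "screen", "with", "standard", "timing")

MARGINAL_PHRASES <- c(
  "a marginally significant effect emerged",
  "the difference approached significance",
  "we observed marginal significance here",
  "the interaction was approaching the threshold",
  "a marginal trend was visible")

DECOY_PHRASES <- c(
  "profit margins narrowed considerably",
  "the approach road was closed",
  "wide margins framed every page",
  "a novel approach was adopted earlier")

#' Synthetic-corpus configuration
#'
#' Validating constructor for the generator. The defaults describe the
#' corpus the pipeline targets: APA-style article bodies from 1985-2016,
#' about 17.6 reported p-values per article, roughly 5.5% of p-values in
#' (.05, .10], and close to 40% of in-range p-values accompanied by a
#' marginal phrase within 200 characters.
#'
#' @param n_articles number of articles.
#' @param journals data frame with columns \code{name}, \code{old_name}
#'   (historical alias or NA), \code{disciplines} (semicolon list),
#'   \code{core_only}, \code{weight}; defaults to [sim_journals_default()].
#' @param year_range inclusive publication-year range.
#' @param pvalues_per_article_mean Poisson mean of reports per article.
#' @param inrange_fraction probability a generated p-value lies in
#'   (.05, .10].
#' @param theta_marginal probability an in-range p-value gets a marginal
#'   phrase within its window.
#' @param theta_trend additive drift of \code{theta_marginal} per year since
#'   \code{year_range[1]} (the effective theta is clamped to [0, 1]).
#' @param decoy_rate probability a report gets a stem-bearing decoy phrase.
#' @param decoy_in_window place decoys inside the window (distance 1-200;
#'   quantifies the method's false positives) instead of outside (201-400).
#' @param misreport_rate probability of a too-high misreported value (1.2).
#' @param doi_rate probability an article carries a DOI.
#' @param meta_missing_rate probability that journal or year is missing from
#'   an article's metadata (resolvable via [sim_resolver()]).
#' @param alias_rate probability a journal appears under its historical name.
#' @param sign_mix named probabilities over the comparison signs.
#' @param seed integer seed; a fixed seed yields a byte-identical corpus.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_articles = 500,
                       journals = sim_journals_default(),
                       year_range = c(1985L, 2016L),
                       pvalues_per_article_mean = 17.59,
                       inrange_fraction = 0.055,
                       theta_marginal = 0.396,
                       theta_trend = 0,
                       decoy_rate = 0.02,
                       decoy_in_window = FALSE,
                       misreport_rate = 0.01,
                       doi_rate = 0.999,
                       meta_missing_rate = 0.005,
                       alias_rate = 0.15,
                       sign_mix = c("<" = 0.4, "=" = 0.5, ">" = 0.1),
                       seed = 1L) {
  cfg <- list(n_articles = n_articles, journals = journals,
              year_range = year_range,
              pvalues_per_article_mean = pvalues_per_article_mean,
              inrange_fraction = inrange_fraction,
              theta_marginal = theta_marginal, theta_trend = theta_trend,
              decoy_rate = decoy_rate, decoy_in_window = decoy_in_window,
              misreport_rate = misreport_rate, doi_rate = doi_rate,
              meta_missing_rate = meta_missing_rate, alias_rate = alias_rate,
              sign_mix = sign_mix, seed = seed)
  for (f in c("inrange_fraction", "theta_marginal", "decoy_rate",
              "misreport_rate", "doi_rate", "meta_missing_rate",
              "alias_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid config field ", f, ": must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(n_articles) || n_articles < 0) {
    stop("invalid config field n_articles", call. = FALSE)
  }
  if (cfg$pvalues_per_article_mean <= 0) {
    stop("invalid config field pvalues_per_article_mean", call. = FALSE)
  }
  if (length(year_range) != 2 || year_range[1] > year_range[2]) {
    stop("invalid config field year_range", call. = FALSE)
  }
  if (abs(sum(sign_mix) - 1) > 1e-8 ||
      !all(names(sign_mix) %in% c("<", "=", ">"))) {
    stop("invalid config field sign_mix", call. = FALSE)
  }
  need <- c("name", "disciplines", "core_only", "weight")
  if (!all(need %in% names(journals))) {
    stop("invalid config field journals: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"old_name" %in% names(journals)) journals$old_name <- NA_character_
  cfg$journals <- journals
  structure(cfg, class = "sim_config")
}

#' Default synthetic journal panel
#'
#' Nine discipline journals (one per APA-style discipline id, with one
#' journal belonging to two disciplines), one core-of-psychology-only
#' journal, and two historical aliases. All names are synthetic.
#'
#' @return data frame usable as the \code{journals} field of [sim_config()].
#' @export
sim_journals_default <- function() {
  data.frame(
    name = c("Journal of Synthetic Social Psychology",
             "Synthetic Developmental Psychology",
             "Synthetic Cognition and Brain",
             "Synthetic Clinical Reports",
             "Synthetic Educational Measurement",
             "Synthetic Experimental Bulletin",
             "Synthetic Forensic Review",
             "Synthetic Health Psychology",
             "Synthetic Organizational Studies",
             "Synthetic General Psychologist"),
    old_name = c("Journal of Synthetic Social Research", NA, NA, NA, NA,
                 "Bulletin of Synthetic Experiments", NA, NA, NA, NA),
    disciplines = c("social", "developmental", "cognitive", "clinical",
                    "educational", "experimental;cognitive", "forensic",
                    "health", "organizational", ""),
    core_only = c(rep(FALSE, 9), TRUE),
    weight = c(3, 2, 2, 3, 2, 3, 1, 2, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' Journal registry implied by a simulation config
#'
#' Builds the [read_journal_registry()] object matching a synthetic corpus:
#' one entry per canonical journal plus one per historical alias.
#'
#' @param config a \code{sim_config}.
#' @return a \code{journal_registry}.
#' @export
sim_registry <- function(config) {
  j <- config$journals
  reg <- data.frame(raw_name = j$name, canonical_name = j$name,
                    disciplines = j$disciplines, core_only = j$core_only,
                    stringsAsFactors = FALSE)
  alias <- !is.na(j$old_name)
  if (any(alias)) {
    reg <- rbind(reg, data.frame(raw_name = j$old_name[alias],
                                 canonical_name = j$name[alias],
                                 disciplines = j$disciplines[alias],
                                 core_only = j$core_only[alias],
                                 stringsAsFactors = FALSE))
  }
  read_journal_registry(reg)
}

#' Metadata resolver for a synthetic corpus
#'
#' Returns a resolver closure (DOI -> journal/year) backed by the generated
#' article table, for use with [complete_metadata()] in tests and synthetic
#' runs.
#'
#' @param articles article data frame from [generate_corpus()] (the
#'   generator stores the complete metadata in attributes, so gaps in the
#'   visible metadata are recoverable).
#' @return function of one DOI returning \code{list(journal =, year =)}.
#' @export
sim_resolver <- function(articles) {
  full <- attr(articles, "full_metadata")
  function(doi) {
    i <- match(doi, full$doi)
    if (is.na(i)) stop("unknown DOI: ", doi, call. = FALSE)
    list(journal = full$journal[i], year = full$year[i])
  }
}

# exact-length filler: starts and ends with a space (n >= 2), so it never
# glues onto a neighbouring token or word
filler_chars <- function(n, base) {
  if (n <= 0) return("")
  if (n == 1) return(" ")
  paste0(" ", substr(base, 1, n - 2), " ")
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces article bodies plus a per-mention ground-truth table: exact
#' 0-based character offset of every generated p-value report, its printed
#' value and comparison sign, range membership, whether a marginal phrase
#' was placed within the 200-character window (and at which distance), and
#' decoy placement. Deterministic for a fixed seed; the caller's RNG state
#' is untouched.
#'
#' @param config a [sim_config()].
#' @return list with \code{articles} (corpus data frame: \code{article_id},
#'   \code{doi}, \code{journal_raw}, \code{year}, \code{text}; complete
#'   metadata retained in the \code{full_metadata} attribute) and
#'   \code{truth} (one row per generated report).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  base_filler <- paste(rep(paste(FILLER_BANK, collapse = " "), 5),
                       collapse = " ")  # ~1.5k chars, stem-free
  jr <- config$journals
  n <- config$n_articles
  j_idx <- sample.int(nrow(jr), n, replace = TRUE, prob = jr$weight)
  years <- sample(seq(config$year_range[1], config$year_range[2]), n,
                  replace = TRUE)
  has_doi <- runif(n) < config$doi_rate
  use_alias <- runif(n) < config$alias_rate & !is.na(jr$old_name[j_idx])
  journal_true <- jr$name[j_idx]
  journal_raw <- ifelse(use_alias, jr$old_name[j_idx], journal_true)
  doi <- ifelse(has_doi, sprintf("10.9999/synth.%06d", seq_len(n)),
                NA_character_)
  # articles without DOI lose journal and year too half the time, feeding
  # the missing-metadata stage; with DOI, small gaps feed the resolver
  drop_all <- !has_doi & runif(n) < 0.5
  miss_j <- (runif(n) < config$meta_missing_rate & has_doi) | drop_all
  miss_y <- (runif(n) < config$meta_missing_rate & has_doi) | drop_all

  n_p <- rpois(n, config$pvalues_per_article_mean)
  sign_names <- names(config$sign_mix)

  texts <- character(n)
  truth_list <- vector("list", n)
  inrange_grid <- seq(0.051, 0.100, by = 0.001)
  low_grid <- seq(0.001, 0.050, by = 0.001)
  high_grid <- seq(0.101, 0.999, by = 0.001)

  for (i in seq_len(n)) {
    k <- n_p[i]
    theta <- config$theta_marginal +
      (years[i] - config$year_range[1]) * config$theta_trend
    theta <- min(1, max(0, theta))
    pieces <- character(0)
    pos <- 0L
    add <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s, type = "chars")
    }
    add(filler_chars(sample(300:450, 1), base_filler))
    v_offset <- integer(k); v_raw <- character(k); v_sign <- character(k)
    v_vt <- character(k); v_inr <- logical(k); v_int <- logical(k)
    v_phr <- rep(NA_character_, k); v_side <- rep(NA_character_, k)
    v_pd <- rep(NA_integer_, k); v_dec <- logical(k)
    v_dd <- rep(NA_integer_, k)
    for (j in seq_len(k)) {
      u <- runif(1)
      if (u < config$misreport_rate) {
        value_text <- sample(c("1.2", "1.5", "2.31"), 1)
        inr <- FALSE
      } else if (u < config$misreport_rate +
                 (1 - config$misreport_rate) * config$inrange_fraction) {
        v <- sample(inrange_grid, 1)
        value_text <- sprintf("%.3f", v)
        if (runif(1) < 0.5) value_text <- sub("^0", "", value_text)
        inr <- TRUE
      } else {
        v <- if (runif(1) < 0.6) sample(low_grid, 1) else sample(high_grid, 1)
        value_text <- sprintf("%.3f", v)
        if (runif(1) < 0.5) value_text <- sub("^0", "", value_text)
        inr <- FALSE
      }
      sign <- sample(sign_names, 1, prob = config$sign_mix)
      fmt <- sample(1:4, 1)
      pstr <- switch(fmt,
                     paste0("p ", sign, " ", value_text),
                     paste0("p", sign, value_text),
                     paste0("*p* ", sign, " ", value_text),
                     paste0("P ", sign, " ", value_text))
      p_off <- if (fmt == 3) 1L else 0L
      raw <- substring(pstr, p_off + 1L)

      intended <- inr && runif(1) < theta
      phrase <- NA_character_
      phrase_side <- NA_character_
      phrase_dist <- NA_integer_
      is_decoy <- runif(1) < config$decoy_rate
      decoy_phrase <- NA_character_
      decoy_side <- NA_character_
      decoy_dist <- NA_integer_
      if (intended) {
        phrase <- sample(MARGINAL_PHRASES, 1)
        phrase_side <- sample(c("before", "after"), 1)
      }
      if (is_decoy) {
        decoy_phrase <- sample(DECOY_PHRASES, 1)
        decoy_side <- if (!is.na(phrase_side)) {
          setdiff(c("before", "after"), phrase_side)
        } else {
          sample(c("before", "after"), 1)
        }
      }

      # ---- before side ----
      if (identical(decoy_side, "before")) {
        dlen <- nchar(decoy_phrase, type = "chars")
        if (config$decoy_in_window) {
          gap <- sample(seq_len(200L - dlen - 2L), 1)
          decoy_dist <- gap + p_off
        } else {
          gap <- sample(201:400, 1)
          decoy_dist <- gap + p_off
        }
        add(decoy_phrase)
        add(filler_chars(gap, base_filler))
      }
      if (identical(phrase_side, "before")) {
        plen <- nchar(phrase, type = "chars")
        gap <- sample(seq_len(200L - plen - 2L), 1)
        phrase_dist <- gap + p_off
        add(phrase)
        add(filler_chars(gap, base_filler))
      }
      offset <- pos + p_off
      add(pstr)
      # ---- after side ----
      if (identical(phrase_side, "after")) {
        plen <- nchar(phrase, type = "chars")
        gap <- sample(seq_len(200L - plen), 1)
        phrase_dist <- gap
        add(filler_chars(gap, base_filler))
        add(phrase)
      }
      if (identical(decoy_side, "after")) {
        dlen <- nchar(decoy_phrase, type = "chars")
        gap <- if (config$decoy_in_window) {
          sample(seq_len(200L - dlen), 1)
        } else {
          sample(201:400, 1)
        }
        decoy_dist <- gap
        add(filler_chars(gap, base_filler))
        add(decoy_phrase)
      }
      add(filler_chars(sample(450:650, 1), base_filler))

      v_offset[j] <- offset; v_raw[j] <- raw; v_sign[j] <- sign
      v_vt[j] <- value_text; v_inr[j] <- inr; v_int[j] <- intended
      v_phr[j] <- phrase; v_side[j] <- phrase_side; v_pd[j] <- phrase_dist
      v_dec[j] <- is_decoy; v_dd[j] <- decoy_dist
    }
    add(filler_chars(sample(200:300, 1), base_filler))
    texts[i] <- paste(pieces, collapse = "")
    truth_list[[i]] <- if (k > 0) {
      list(article_id = rep(sprintf("art%06d", i), k),
           journal = rep(journal_true[i], k), year = rep(years[i], k),
           offset = v_offset, raw = v_raw, comparison = v_sign,
           value_text = v_vt, value = as.numeric(v_vt), in_range = v_inr,
           intended_marginal = v_int, phrase = v_phr, phrase_side = v_side,
           phrase_distance = v_pd, is_decoy = v_dec, decoy_distance = v_dd,
           decoy_in_window = v_dec & config$decoy_in_window)
    }
  }

  articles <- data.frame(
    article_id = sprintf("art%06d", seq_len(n)),
    doi = doi,
    journal_raw = ifelse(miss_j, NA_character_, journal_raw),
    year = ifelse(miss_y, NA_integer_, years),
    text = texts,
    stringsAsFactors = FALSE
  )
  attr(articles, "full_metadata") <- data.frame(
    article_id = articles$article_id, doi = doi, journal = journal_raw,
    year = years, stringsAsFactors = FALSE)
  truth_list <- truth_list[!vapply(truth_list, is.null, logical(1))]
  truth <- if (length(truth_list)) {
    cols <- names(truth_list[[1]])
    out <- lapply(cols, function(cn) {
      unlist(lapply(truth_list, `[[`, cn), use.names = FALSE)
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  if (is.null(truth)) {
    truth <- data.frame(article_id = character(0), journal = character(0),
                        year = integer(0), offset = integer(0),
                        raw = character(0), comparison = character(0),
                        value_text = character(0), value = numeric(0),
                        in_range = logical(0), intended_marginal = logical(0),
                        phrase = character(0), phrase_side = character(0),
                        phrase_distance = integer(0), is_decoy = logical(0),
                        decoy_distance = integer(0),
                        decoy_in_window = logical(0), stringsAsFactors = FALSE)
  }
  list(articles = articles, truth = truth)
}

#' Compare pipeline output with ground truth
#'
#' Matches extracted mentions to generated reports on (article_id, offset)
#' and reports extraction recall and precision, classifier agreement with
#' the intended labels on in-range mentions, and the decoy false-positive
#' rate (share of in-range mentions without an intended marginal phrase but
#' with an in-window decoy that the classifier nonetheless labels marginal).
#'
#' @param truth ground-truth table from [generate_corpus()].
#' @param records labeled record data frame (after [classify_records()]).
#' @return list with \code{extraction_recall}, \code{extraction_precision},
#'   \code{label_agreement}, \code{decoy_false_positive_rate}.
#' @export
truth_compare <- function(truth, records) {
  tkey <- paste(truth$article_id, truth$offset)
  rkey <- paste(records$article_id, records$offset)
  recall <- if (nrow(truth)) mean(tkey %in% rkey) else NA_real_
  precision <- if (nrow(records)) mean(rkey %in% tkey) else NA_real_
  idx <- match(tkey, rkey)
  matched <- !is.na(idx)
  lab <- records$is_marginal[idx[matched]]
  tm <- truth$intended_marginal[matched]
  tinr <- truth$in_range[matched]
  use <- tinr & !is.na(lab)
  agreement <- if (any(use)) mean(lab[use] == tm[use]) else NA_real_
  dec <- use & !tm & truth$is_decoy[matched] & truth$decoy_in_window[matched]
  decoy_fp <- if (any(dec)) mean(lab[dec]) else NA_real_
  list(extraction_recall = recall,
       extraction_precision = precision,
       label_agreement = agreement,
       decoy_false_positive_rate = decoy_fp)
}
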