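# Trial corpus data model: construction, validation, readers/writers.
#
# A corpus couples a trials table (one row per published trial) with an
# optional articles table (per-section full text for the SGR subsample).
# Trials carry nested author lists (full_name, position) and one ISO3
# affiliation country per author.

#' Construct a trial corpus
#'
#' Validates a trials table (and optional articles table) and returns a
#' `trial_corpus` object. Duplicate registry identifiers are collapsed to
#' their first occurrence with a warning, mirroring deduplication on the
#' secondary source ID.
#'
#' @param trials Tibble with columns `trial_id`, `pub_year`, `pub_month`,
#'   `entity`, `hf_subtype` (NA unless entity is HeartFailure), `n_women`,
#'   `n_men`, `authors` (list column of tibbles with `full_name`, `position`),
#'   `countries` (list column of ISO3 character vectors, one per author).
#' @param articles Optional tibble with columns `trial_id`, `title`,
#'   `abstract`, `methods`, `results`, `discussion`, `supplementary`,
#'   `has_demographics_table_sex`, `reports_adverse_events`.
#' @param provenance Free-text metadata string.
#' @param year_range Permitted publication-year window (inclusive).
#' @return A `trial_corpus` object: list with elements `trials`, `articles`,
#'   `provenance`.
#' @export
new_corpus <- function(trials, articles = NULL, provenance = "",
                       year_range = c(2018L, 2024L)) {
  trials <- as_tibble(trials)
  if (anyDuplicated(trials$trial_id)) {
    dups <- unique(trials$trial_id[duplicated(trials$trial_id)])
    warn(sprintf("duplicate trial_id collapsed to first occurrence: %s",
                 paste(dups, collapse = ", ")))
    trials <- trials[!duplicated(trials$trial_id), ]
  }
  validate_trials(trials, year_range)
  if (!is.null(articles) && nrow(as_tibble(articles)) > 0) {
    articles <- validate_articles(as_tibble(articles), trials$trial_id)
  } else {
    articles <- NULL
  }
  structure(list(trials = trials, articles = articles,
                 provenance = provenance),
            class = "trial_corpus")
}

#' @export
print.trial_corpus <- function(x, ...) {
  cat(sprintf("<trial_corpus> %d trials, %d articles with full text\n",
              nrow(x$trials),
              if (is.null(x$articles)) 0L else nrow(x$articles)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

row_abort <- function(i, field, msg) {
  abort(sprintf("trial row %d, field '%s': %s", i, field, msg),
        class = "equitrial_validation_error")
}

validate_trials <- function(trials, year_range = c(2018L, 2024L)) {
  needed <- c("trial_id", "pub_year", "pub_month", "entity", "hf_subtype",
              "n_women", "n_men", "authors", "countries")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    abort(paste("trials table missing column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "equitrial_validation_error")
  if (nrow(trials) == 0) return(invisible(trials))
  first_bad <- function(flag) if (any(flag)) which(flag)[1] else 0L
  i <- first_bad(is.na(trials$trial_id) | !nzchar(trials$trial_id))
  if (i) row_abort(i, "trial_id", "empty identifier")
  i <- first_bad(is.na(trials$n_women) | trials$n_women < 0)
  if (i) row_abort(i, "n_women", "negative or missing count")
  i <- first_bad(is.na(trials$n_men) | trials$n_men < 0)
  if (i) row_abort(i, "n_men", "negative or missing count")
  i <- first_bad(trials$n_women + trials$n_men < 1)
  if (i) row_abort(i, "n_women", "trial must have at least one participant")
  i <- first_bad(is.na(trials$pub_year) | trials$pub_year < year_range[1] |
                   trials$pub_year > year_range[2])
  if (i) row_abort(i, "pub_year", sprintf("outside window %d-%d",
                                          year_range[1], year_range[2]))
  i <- first_bad(is.na(trials$pub_month) | trials$pub_month < 1 |
                   trials$pub_month > 12)
  if (i) row_abort(i, "pub_month", "must be in 1..12")
  i <- first_bad(!trials$entity %in% cvd_entities())
  if (i) row_abort(i, "entity",
                   sprintf("unknown entity '%s'", trials$entity[i]))
  sub <- trials$hf_subtype
  i <- first_bad(!is.na(sub) & trials$entity != "HeartFailure")
  if (i) row_abort(i, "hf_subtype", "present but entity is not HeartFailure")
  i <- first_bad(!is.na(sub) & !sub %in% hf_subtypes())
  if (i) row_abort(i, "hf_subtype",
                   sprintf("unknown subtype '%s'", sub[i]))
  for (i in seq_len(nrow(trials))) {
    au <- trials$authors[[i]]
    if (is.null(au) || nrow(au) == 0)
      row_abort(i, "authors", "author list is empty")
    if (!all(c("full_name", "position") %in% names(au)))
      row_abort(i, "authors", "needs columns full_name, position")
    pos <- au$position
    if (!all(pos %in% c("first", "last", "interior")))
      row_abort(i, "authors", "positions must be first/last/interior")
    n_first <- sum(pos == "first")
    n_last <- sum(pos == "last")
    if (length(pos) == 1) {
      # a single author holds both leading positions; stored as "first"
      if (n_first != 1)
        row_abort(i, "authors", "single author must have position 'first'")
    } else if (n_first != 1 || n_last != 1) {
      row_abort(i, "authors", "exactly one first and one last author required")
    }
    if (length(trials$countries[[i]]) != length(pos))
      row_abort(i, "countries", "one ISO3 code per author required")
  }
  invisible(trials)
}

validate_articles <- function(articles, trial_ids) {
  needed <- c("trial_id", "title", "abstract", "methods", "results",
              "discussion", "supplementary", "has_demographics_table_sex",
              "reports_adverse_events")
  missing_cols <- setdiff(needed, names(articles))
  if (length(missing_cols))
    abort(paste("articles table missing column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "equitrial_validation_error")
  orphan <- setdiff(articles$trial_id, trial_ids)
  if (length(orphan))
    abort(sprintf("article trial_id(s) with no matching trial: %s",
                  paste(orphan, collapse = ", ")),
          class = "equitrial_validation_error")
  if (anyDuplicated(articles$trial_id))
    abort("duplicate trial_id in articles table",
          class = "equitrial_validation_error")
  articles
}

#' Per-trial share of women/female participants
#'
#' @param trials A `trial_corpus`, a trials tibble, or a one-row trial record.
#' @return Numeric vector `n_women / (n_women + n_men)`, one value per trial.
#' @examples
#' trial_women_share(tibble::tibble(n_women = 716569, n_men = 1143167))
#' @export
trial_women_share <- function(trials) {
  if (inherits(trials, "trial_corpus")) trials <- trials$trials
  total <- trials$n_women + trials$n_men
  if (any(total < 1)) abort("trial with zero participants")
  trials$n_women / total
}

# region table ----------------------------------------------------------------

the <- new.env(parent = emptyenv())

#' Packaged country-to-region table
#'
#' ISO3 alpha-3 country codes mapped to the eight World Bank regions.
#' @return Tibble with columns `iso3`, `region`.
#' @export
region_table <- function() {
  if (is.null(the$region_table)) {
    the$region_table <- as_tibble(
      read.csv(extdata_path("country_regions.csv"), stringsAsFactors = FALSE))
  }
  the$region_table
}

#' Majority region of an author affiliation list
#'
#' Maps each author's affiliation country to its World Bank region and returns
#' the region with the plurality of affiliations. Ties are broken in favour of
#' the tied region appearing earliest in the author list (so the first
#' author's region wins a two-way tie).
#'
#' @param countries Character vector of ISO3 codes in author order.
#' @param table Country-to-region table (default: packaged).
#' @return A single region label.
#' @examples
#' majority_region(c("DEU", "CHE", "CHE"))
#' majority_region(c("USA", "DEU")) # tie: first author's region
#' @export
majority_region <- function(countries, table = region_table()) {
  if (length(countries) == 0) abort("empty country list")
  idx <- match(countries, table$iso3)
  if (anyNA(idx))
    abort(sprintf("unknown ISO3 code(s): %s",
                  paste(unique(countries[is.na(idx)]), collapse = ", ")))
  regions <- table$region[idx]
  counts <- table(regions)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  # earliest-listed country among tied regions decides
  first_seen <- vapply(top, function(r) min(which(regions == r)), integer(1))
  top[which.min(first_seen)]
}

# readers / writers -----------------------------------------------------------

pack_authors <- function(authors) {
  vapply(authors, function(a)
    paste(paste(a$full_name, a$position, sep = "|"), collapse = ";"),
    character(1))
}

unpack_authors <- function(x, row) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, "|", fixed = TRUE)
  bad <- lengths(fields) != 2
  if (any(bad))
    row_abort(row, "authors", "expected 'name|position' entries")
  tibble(full_name = vapply(fields, `[[`, character(1), 1),
         position = vapply(fields, `[[`, character(1), 2))
}

#' Write a corpus to disk
#'
#' CSV format writes one row per trial with authors semicolon-joined as
#' `name|position` and countries semicolon-joined ISO3; article texts, when
#' present, go to a companion JSON file. JSON format writes one nested
#' document holding trials, articles and provenance.
#'
#' @param corpus A `trial_corpus`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param articles_path Companion article-text JSON path for CSV format
#'   (default: `<path-sans-ext>_articles.json`, written only if articles exist).
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "json"),
                         articles_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "trial_corpus"))
  if (format == "csv") {
    flat <- corpus$trials
    flat$authors <- pack_authors(flat$authors)
    flat$countries <- vapply(flat$countries, paste, character(1),
                             collapse = ";")
    write.csv(flat, path, row.names = FALSE, na = "")
    written <- path
    if (!is.null(corpus$articles)) {
      if (is.null(articles_path))
        articles_path <- paste0(tools::file_path_sans_ext(path),
                                "_articles.json")
      jsonlite::write_json(corpus$articles, articles_path, auto_unbox = TRUE,
                           na = "null", digits = NA)
      written <- c(written, articles_path)
    }
    invisible(written)
  } else {
    doc <- list(
      provenance = corpus$provenance,
      trials = purrr::pmap(corpus$trials, function(...) {
        t <- list(...)
        list(trial_id = t$trial_id, pub_year = t$pub_year,
             pub_month = t$pub_month, entity = t$entity,
             hf_subtype = t$hf_subtype, n_women = t$n_women,
             n_men = t$n_men,
             authors = t$authors, countries = t$countries)
      }),
      articles = corpus$articles)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null",
                         digits = NA)
    invisible(path)
  }
}

#' Load a corpus from disk
#'
#' Inverse of [write_corpus()]. All type invariants are enforced on load;
#' duplicate trial identifiers are collapsed to the first occurrence with a
#' warning. Schema violations raise a validation error naming row and field.
#'
#' @param path Corpus file (CSV or JSON).
#' @param format `"csv"` or `"json"`.
#' @param articles_path Optional companion article-text JSON (CSV format).
#' @return A `trial_corpus`.
#' @export
load_corpus <- function(path, format = c("csv", "json"),
                        articles_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "csv") {
    flat <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = c(trial_id = "character"))
    flat <- as_tibble(flat)
    flat$hf_subtype <- as.character(flat$hf_subtype)
    flat$hf_subtype[!is.na(flat$hf_subtype) & flat$hf_subtype == ""] <- NA
    flat$authors <- purrr::imap(flat$authors, unpack_authors)
    flat$countries <- strsplit(as.character(flat$countries), ";", fixed = TRUE)
    articles <- NULL
    if (!is.null(articles_path)) articles <- read_articles(articles_path)
    new_corpus(flat, articles)
  } else {
    doc <- jsonlite::read_json(path)
    trials <- purrr::map(doc$trials, function(t) {
      au <- purrr::map(t$authors, as_tibble)
      tibble(trial_id = t$trial_id,
             pub_year = as.integer(t$pub_year),
             pub_month = as.integer(t$pub_month),
             entity = t$entity,
             hf_subtype = if (is.null(t$hf_subtype)) NA_character_
                          else t$hf_subtype,
             n_women = as.integer(t$n_women),
             n_men = as.integer(t$n_men),
             authors = list(bind_rows(au)),
             countries = list(unlist(t$countries)))
    })
    trials <- bind_rows(trials)
    articles <- if (!is.null(doc$articles) && length(doc$articles))
      articles_from_list(doc$articles) else NULL
    new_corpus(trials, articles,
               provenance = doc$provenance %||% "")
  }
}

articles_from_list <- function(lst) {
  bind_rows(purrr::map(lst, function(a) {
    tibble(trial_id = a$trial_id,
           title = a$title %||% "", abstract = a$abstract %||% "",
           methods = a$methods %||% "", results = a$results %||% "",
           discussion = a$discussion %||% "",
           supplementary = a$supplementary %||% "",
           has_demographics_table_sex =
             isTRUE(as.logical(a$has_demographics_table_sex)),
           reports_adverse_events =
             isTRUE(as.logical(a$reports_adverse_events)))
  }))
}

#' Read article texts from JSON
#' @param path Article JSON file written by [write_corpus()].
#' @return Articles tibble.
#' @export
read_articles <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  articles_from_list(jsonlite::read_json(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
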