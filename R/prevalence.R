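# Prevalence lookup and participation-prevalence ratio (PPR).
#
# The PPR denominator is the women's share among prevalent cases of the
# studied disease (entity), matched by region and year where an entry exists.
# A PPR between 0.8 and 1.2 (inclusive) counts as optimal representation.

#' Packaged default prevalence table
#'
#' Women's share among prevalent cases by disease entity. Heart-failure rows
#' carry the literature values 0.50 (unspecified), 0.42 (HFrEF) and
#' 0.57 (HFpEF); the remaining entities ship ANY-level placeholder values on
#' the scale reported in the epidemiological literature and are meant to be
#' replaced by user-supplied region- and year-specific estimates.
#'
#' @return Tibble with columns `entity`, `region`, `year`,
#'   `women_share_cases`.
#' @export
default_prevalence_table <- function() {
  read_prevalence_table(extdata_path("default_prevalence.csv"))
}

#' Read a prevalence table from CSV
#'
#' Columns: `entity`, `region` (a World Bank region or `ANY`), `year`
#' (integer or `ANY`), `women_share_cases` in (0,1).
#'
#' @param path CSV file path.
#' @return Validated prevalence tibble.
#' @export
read_prevalence_table <- function(path) {
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
  needed <- c("entity", "region", "year", "women_share_cases")
  if (!all(needed %in% names(tab)))
    abort(paste("prevalence table needs columns:",
                paste(needed, collapse = ", ")))
  tab$women_share_cases <- as.numeric(tab$women_share_cases)
  if (any(is.na(tab$women_share_cases)) ||
      any(tab$women_share_cases <= 0 | tab$women_share_cases >= 1))
    abort("women_share_cases must be strictly between 0 and 1")
  tab
}

#' Look up the prevalence share for a trial
#'
#' The most specific entry wins, with fallback order
#' (entity, region, year) -> (entity, region, ANY) -> (entity, ANY, ANY).
#' For HeartFailure trials with an HFrEF/HFpEF subtype, the subtype entry is
#' preferred and the unspecified HeartFailure entry is the fallback.
#'
#' @param table Prevalence tibble (see [read_prevalence_table()]).
#' @param entity Disease-entity label.
#' @param region World Bank region label, or `NULL`.
#' @param year Publication year, or `NULL`.
#' @param hf_subtype Optional HF subtype label.
#' @return One-row tibble: the matched prevalence entry.
#' @export
lookup_prevalence <- function(table, entity, region = NULL, year = NULL,
                              hf_subtype = NULL) {
  if (nrow(table) == 0) abort("prevalence table is empty")
  keys <- entity
  if (identical(entity, "HeartFailure") && !is.null(hf_subtype) &&
      !is.na(hf_subtype) && hf_subtype %in% c("HFrEF", "HFpEF")) {
    keys <- c(hf_subtype, entity)
  }
  year_chr <- if (is.null(year)) NULL else as.character(year)
  for (key in keys) {
    sub <- table[table$entity == key, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (!is.null(region) && !is.null(year_chr)) {
      hit <- sub[sub$region == region & sub$year == year_chr, ]
      if (nrow(hit)) return(hit[1, ])
    }
    if (!is.null(region)) {
      hit <- sub[sub$region == region & sub$year == "ANY", ]
      if (nrow(hit)) return(hit[1, ])
    }
    hit <- sub[sub$region == "ANY" & sub$year == "ANY", ]
    if (nrow(hit)) return(hit[1, ])
  }
  abort(sprintf("no prevalence entry for entity '%s'", entity),
        class = "equitrial_lookup_error")
}

ppr_category <- function(ppr) {
  ifelse(ppr < 0.8, "below", ifelse(ppr > 1.2, "above", "optimal"))
}

#' Compute a participation-prevalence ratio
#'
#' Divides the trial's share of women/female participants by the women's
#' share among prevalent cases. A ratio in \[0.8, 1.2\] (endpoints inclusive)
#' is classified `optimal`; below/above otherwise.
#'
#' @param women_share_trial Proportion of women among trial participants.
#' @param prevalence One-row prevalence entry from [lookup_prevalence()], or
#'   a bare numeric share in (0,1).
#' @return List with `ppr`, `category`, `prevalence_used`.
#' @examples
#' compute_ppr(0.21, 0.42) # ppr 0.5, below
#' @export
compute_ppr <- function(women_share_trial, prevalence) {
  stopifnot(women_share_trial >= 0, women_share_trial <= 1)
  share_cases <- if (is.numeric(prevalence)) prevalence
                 else prevalence$women_share_cases
  stopifnot(share_cases > 0, share_cases < 1)
  ppr <- women_share_trial / share_cases
  list(ppr = ppr, category = ppr_category(ppr),
       prevalence_used = prevalence)
}

#' PPR and category for every trial in a corpus
#'
#' Derives each trial's region from its author affiliations, looks up the
#' matching prevalence entry and computes the PPR.
#'
#' @param corpus A `trial_corpus`.
#' @param prevalence Prevalence table (default: packaged).
#' @param regions Optional precomputed region per trial (character vector);
#'   derived via [majority_region()] when `NULL`.
#' @return Tibble: `trial_id`, `region`, `women_share`, `women_share_cases`,
#'   `ppr`, `category`.
#' @export
ppr_for_corpus <- function(corpus, prevalence = default_prevalence_table(),
                           regions = NULL) {
  trials <- corpus$trials
  if (is.null(regions))
    regions <- vapply(trials$countries, majority_region, character(1))
  share <- trial_women_share(trials)
  if (all(prevalence$region == "ANY" & prevalence$year == "ANY")) {
    # pure entity-level table: vectorised lookup
    key <- ifelse(trials$entity == "HeartFailure" &
                    !is.na(trials$hf_subtype) &
                    trials$hf_subtype %in% c("HFrEF", "HFpEF"),
                  trials$hf_subtype, trials$entity)
    idx <- match(key, prevalence$entity)
    idx[is.na(idx)] <- match(trials$entity[is.na(idx)], prevalence$entity)
    if (anyNA(idx))
      abort(sprintf("no prevalence entry for entity '%s'",
                    trials$entity[which(is.na(idx))[1]]),
            class = "equitrial_lookup_error")
    share_cases <- prevalence$women_share_cases[idx]
  } else {
    share_cases <- vapply(seq_len(nrow(trials)), function(i) {
      lookup_prevalence(prevalence, trials$entity[i], regions[i],
                        trials$pub_year[i],
                        trials$hf_subtype[i])$women_share_cases
    }, numeric(1))
  }
  tibble(trial_id = trials$trial_id, region = regions,
         women_share = share, women_share_cases = share_cases,
         ppr = share / share_cases,
         category = ppr_category(share / share_cases))
}

#' Count trials per PPR category
#'
#' @param results Tibble with a `category` column (from [ppr_for_corpus()]),
#'   or a character vector of categories.
#' @return Named integer vector with entries `below`, `optimal`, `above`.
#' @export
ppr_category_counts <- function(results) {
  cats <- if (is.character(results)) results else results$category
  out <- c(below = 0L, optimal = 0L, above = 0L)
  tab <- table(factor(cats, levels = names(out)))
  out[names(tab)] <- as.integer(tab)
  out
}
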