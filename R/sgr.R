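# Sex/gender-sensitive reporting (SGR) scoring.
#
# Deterministic whole-word keyword scanning of per-section article text.
# Four core subsection flags feed the 0-4 sum: demographics, in-text results
# mention, stratified endpoint analysis, and discussion; a sum >= 3 counts as
# high SGR. Title, abstract and adverse-event stratification are reported
# alongside but do not enter the core sum.

#' Default keyword lexicon
#'
#' The eight match tokens, split by role: six sex/gender terms and two
#' locator terms. `subgroup` gates the endpoint flag and `adverse` gates
#' adverse-event stratification; neither counts as a sex/gender mention on
#' its own. Matching is case-insensitive and whole-word: hyphen and slash
#' act as word boundaries, so "sex/gender" matches both tokens while "men"
#' never matches inside "management" or "women".
#'
#' @param terms Full token list.
#' @param sex_gender_terms Tokens counted as sex/gender mentions.
#' @param locator_terms Tokens used only to gate flags.
#' @return A `keyword_lexicon` list.
#' @export
default_lexicon <- function(terms = c("gender", "sex", "male", "female",
                                      "men", "women", "subgroup", "adverse"),
                            sex_gender_terms = setdiff(terms,
                                                       c("subgroup", "adverse")),
                            locator_terms = intersect(terms,
                                                      c("subgroup", "adverse"))) {
  structure(list(terms = terms, sex_gender_terms = sex_gender_terms,
                 locator_terms = locator_terms),
            class = "keyword_lexicon")
}

#' Read a lexicon override from YAML
#'
#' Expects keys `terms` and optionally `sex_gender_terms`; defaults fill the
#' rest as in [default_lexicon()].
#' @param path YAML file.
#' @return A `keyword_lexicon`.
#' @export
read_lexicon <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$terms)) abort("lexicon YAML needs a 'terms' list")
  terms <- unlist(cfg$terms)
  sg <- if (!is.null(cfg$sex_gender_terms)) unlist(cfg$sex_gender_terms)
        else setdiff(terms, c("subgroup", "adverse"))
  default_lexicon(terms = terms, sex_gender_terms = sg)
}

word_pattern <- function(tokens) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tokens)
  sprintf("(*UCP)(?i)\\b(?:%s)\\b", paste(esc, collapse = "|"))
}

# endpoint locators are matched as prefixes so "stratified", "adjustment",
# "subgroups" qualify
endpoint_locator_pattern <- "(*UCP)(?i)\\b(?:subgroup|interaction|stratif|adjust)"
demographics_cue_pattern <- "(*UCP)(?i)\\b(?:baseline|characteristic)"

split_sentences <- function(text) {
  text <- text[!is.na(text)]
  if (!length(text) || !nzchar(paste(text, collapse = "")))
    return(character(0))
  unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
}

#' Find lexicon terms in a text
#'
#' Whole-word, case-insensitive matching of every lexicon token, with match
#' positions. Singular/plural variants are not expanded.
#'
#' @param text A single character string (may be empty).
#' @param lexicon A `keyword_lexicon`.
#' @return Tibble with columns `term`, `start`, `end` (byte positions),
#'   zero rows when nothing matches.
#' @examples
#' find_terms("Women and men differed by sex")
#' @export
find_terms <- function(text, lexicon = default_lexicon()) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text))
    return(tibble(term = character(0), start = integer(0), end = integer(0)))
  out <- purrr::map(lexicon$terms, function(tok) {
    m <- gregexpr(word_pattern(tok), text, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(term = tok, start = as.integer(m),
           end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(term = character(0), start = integer(0),
                  end = integer(0)))
  arrange(res, .data$start)
}

# vectorised helpers over a character vector of section texts ----------------

match_any <- function(texts, pattern) {
  out <- !is.na(texts) & grepl(pattern, texts, perl = TRUE)
  out
}

# TRUE per element iff some sentence matches both patterns
sentence_cooccur <- function(texts, pat_a, pat_b) {
  texts[is.na(texts)] <- ""
  sent <- strsplit(texts, "(?<=[.!?])\\s+", perl = TRUE)
  ns <- lengths(sent)
  if (sum(ns) == 0) return(rep(FALSE, length(texts)))
  id <- rep.int(seq_along(texts), ns)
  flat <- unlist(sent)
  hit <- grepl(pat_a, flat, perl = TRUE) & grepl(pat_b, flat, perl = TRUE)
  out <- rep(FALSE, length(texts))
  if (any(hit)) out[unique(id[hit])] <- TRUE
  out
}

paste_sections <- function(a, b) {
  a[is.na(a)] <- ""
  b[is.na(b)] <- ""
  paste(a, b, sep = " ")
}

#' Score SGR for a table of article texts
#'
#' Vectorised scorer behind [score_article()]. Flags:
#' * `title_flag`, `abstract_flag`: sex/gender term in title/abstract.
#' * `demographics_flag`: curated baseline-table indicator, or (fallback
#'   heuristic) a methods/results sentence combining a sex/gender term with
#'   "baseline"/"characteristics"; `demographics_source` records which.
#' * `results_text_flag`: sex/gender term anywhere in methods or results.
#' * `endpoint_flag`: sex/gender term in the same sentence as a subgroup/
#'   interaction/stratification/adjustment locator, in results or
#'   supplementary material.
#' * `discussion_flag`: sex/gender term in the discussion (limitations
#'   included).
#' * `adverse_stratified_flag`: sex/gender term in the same sentence as an
#'   "adverse" match (results or supplementary); `NA` when the article does
#'   not report adverse events.
#'
#' `core_sum` adds the four core flags (demographics, results, endpoint,
#' discussion); `high_sgr` is `core_sum >= 3`. Missing sections score as
#' empty text.
#'
#' @param articles Articles tibble (see [new_corpus()]).
#' @param lexicon A `keyword_lexicon`.
#' @return Tibble of per-article flags, `core_sum` and `high_sgr`.
#' @export
score_articles <- function(articles, lexicon = default_lexicon()) {
  a <- as_tibble(articles)
  sg <- word_pattern(lexicon$sex_gender_terms)
  adverse <- word_pattern("adverse")
  methods_results <- paste_sections(a$methods, a$results)
  results_suppl <- paste_sections(a$results, a$supplementary)

  title_flag <- match_any(a$title, sg)
  abstract_flag <- match_any(a$abstract, sg)
  results_text_flag <- match_any(methods_results, sg)
  demo_heuristic <- sentence_cooccur(methods_results, sg,
                                     demographics_cue_pattern)
  demographics_flag <- a$has_demographics_table_sex | demo_heuristic
  demographics_source <- ifelse(a$has_demographics_table_sex, "curated",
                                ifelse(demo_heuristic, "heuristic", NA))
  endpoint_flag <- sentence_cooccur(results_suppl, sg,
                                    endpoint_locator_pattern)
  discussion_flag <- match_any(a$discussion, sg)
  adverse_hit <- sentence_cooccur(results_suppl, sg, adverse)
  adverse_stratified_flag <- ifelse(a$reports_adverse_events, adverse_hit, NA)

  core_sum <- as.integer(demographics_flag) + as.integer(results_text_flag) +
    as.integer(endpoint_flag) + as.integer(discussion_flag)
  tibble(trial_id = a$trial_id,
         title_flag = title_flag, abstract_flag = abstract_flag,
         demographics_flag = demographics_flag,
         demographics_source = demographics_source,
         results_text_flag = results_text_flag,
         endpoint_flag = endpoint_flag,
         discussion_flag = discussion_flag,
         adverse_stratified_flag = adverse_stratified_flag,
         reports_adverse_events = a$reports_adverse_events,
         core_sum = core_sum,
         high_sgr = core_sum >= 3L)
}

#' Score a single article
#'
#' @param article One-row articles tibble or named list of sections.
#' @param lexicon A `keyword_lexicon`.
#' @return One-row SGR score tibble (see [score_articles()]).
#' @export
score_article <- function(article, lexicon = default_lexicon()) {
  if (!is.data.frame(article)) article <- as_tibble(article)
  stopifnot(nrow(article) == 1)
  score_articles(article, lexicon)
}

#' Score every full-text article in a corpus
#'
#' @param corpus A `trial_corpus` with articles.
#' @param lexicon A `keyword_lexicon`.
#' @return SGR score tibble joined with each trial's `pub_year` and `entity`.
#' @export
score_corpus <- function(corpus, lexicon = default_lexicon()) {
  if (is.null(corpus$articles)) abort("corpus has no article texts")
  scores <- score_articles(corpus$articles, lexicon)
  left_join(scores,
            select(corpus$trials, "trial_id", "pub_year", "entity"),
            by = "trial_id")
}

#' Summarise SGR scores by group
#'
#' Shares of each flag, the distribution of the 0-4 core sum, and the share
#' of high-SGR articles, overall or per publication year / disease entity.
#' The adverse-event share uses only articles that report adverse events as
#' its denominator.
#'
#' @param scores Score tibble from [score_corpus()] (needs `pub_year` /
#'   `entity` columns for the grouped variants).
#' @param group_by `"none"`, `"year"` or `"entity"`.
#' @return Tibble, one row per group.
#' @export
corpus_sgr_summary <- function(scores, group_by = c("none", "year", "entity")) {
  group_by <- match.arg(group_by)
  if (nrow(scores) == 0) abort("empty score list")
  key <- switch(group_by,
                none = rep("all", nrow(scores)),
                year = as.character(scores$pub_year),
                entity = scores$entity)
  if (anyNA(key)) {
    warn("articles with missing group value omitted from SGR summary")
    scores <- scores[!is.na(key), ]
    key <- key[!is.na(key)]
  }
  scores$group <- key
  out <- scores %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      share_title = mean(.data$title_flag),
      share_abstract = mean(.data$abstract_flag),
      share_demographics = mean(.data$demographics_flag),
      share_results = mean(.data$results_text_flag),
      share_endpoint = mean(.data$endpoint_flag),
      share_discussion = mean(.data$discussion_flag),
      n_adverse_reporting = sum(.data$reports_adverse_events),
      share_adverse_stratified =
        if (sum(.data$reports_adverse_events) > 0)
          mean(.data$adverse_stratified_flag[.data$reports_adverse_events])
        else NA_real_,
      share_sum_0 = mean(.data$core_sum == 0L),
      share_sum_1 = mean(.data$core_sum == 1L),
      share_sum_2 = mean(.data$core_sum == 2L),
      share_sum_3 = mean(.data$core_sum == 3L),
      share_sum_4 = mean(.data$core_sum == 4L),
      share_high_sgr = mean(.data$high_sgr),
      .groups = "drop")
  out
}
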