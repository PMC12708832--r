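# Author sex/gender designation by name lookup, and per-trial profiles.
#
# Designation is name-based, via a user-supplied (or packaged synthetic)
# lookup of normalized given names with a confidence threshold; it is a
# designation with documented error, not an inference of gender identity.

# normalized given name, or NA for initials-only names
normalize_given_name <- function(name) {
  name <- trimws(name)
  token <- sub("\\s.*$", "", name)
  token <- gsub("[,;]", "", token)
  # "J.", "J", "J.-P." are initials, not given names
  if (!nzchar(token) || grepl("^([[:alpha:]][.]?([-][[:alpha:]][.]?)*)$",
                              token) && nchar(gsub("[.-]", "", token)) <= 2 &&
      grepl("[.]", token) ||
      nchar(gsub("[.-]", "", token)) <= 1)
    return(NA_character_)
  token <- tolower(token)
  folded <- iconv(token, from = "UTF-8", to = "ASCII//TRANSLIT")
  if (!is.na(folded)) token <- folded
  # transliteration can leave apostrophes etc. behind; keys are letters only
  token <- gsub("[^a-z]", "", token)
  if (!nzchar(token)) return(NA_character_)
  token
}

#' Packaged synthetic name-to-gender lookup
#'
#' A synthetic lookup covering the given names used by the corpus generator
#' at confidence 0.97, plus a few deliberately ambiguous low-confidence
#' entries. Real analyses should supply their own validated lookup via
#' [read_gender_lookup()].
#'
#' @return Tibble with columns `name`, `label`, `confidence`.
#' @export
default_gender_lookup <- function() {
  tibble(
    name = c(tolower(woman_name_pool()), tolower(man_name_pool()),
             "andrea", "kim", "sasha"),
    label = c(rep("woman_female", length(woman_name_pool())),
              rep("man_male", length(man_name_pool())),
              "woman_female", "woman_female", "man_male"),
    confidence = c(rep(0.97, length(woman_name_pool()) +
                         length(man_name_pool())),
                   0.55, 0.60, 0.52))
}

#' Read a name-gender lookup from CSV
#'
#' Columns: `name`, `label` (`woman_female` / `man_male`), `confidence` in
#' \[0,1\]. Names are normalized (lowercase, diacritics folded) on load.
#'
#' @param path CSV file.
#' @return Lookup tibble.
#' @export
read_gender_lookup <- function(path) {
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("name", "label", "confidence") %in% names(tab)))
    abort("gender lookup needs columns name, label, confidence")
  if (!all(tab$label %in% c("woman_female", "man_male")))
    abort("lookup labels must be woman_female or man_male")
  if (any(tab$confidence < 0 | tab$confidence > 1))
    abort("lookup confidence must lie in [0,1]")
  tab$name <- vapply(tab$name, function(n) {
    f <- iconv(tolower(trimws(n)), from = "UTF-8", to = "ASCII//TRANSLIT")
    if (is.na(f)) f <- tolower(trimws(n))
    gsub("[^a-z]", "", f)
  }, character(1), USE.NAMES = FALSE)
  tab
}

#' Designate author sex/gender from a full name
#'
#' Extracts the given name (first whitespace token), normalizes it, and
#' resolves it through the lookup. Initials-only given names, names absent
#' from the lookup, and entries below the confidence threshold all resolve
#' to `"unknown"`.
#'
#' @param name Character vector of full names.
#' @param lookup Lookup tibble (default: packaged synthetic lookup).
#' @param min_confidence Threshold below which entries resolve to unknown
#'   (default 0.8).
#' @return Character vector: `woman_female`, `man_male` or `unknown`.
#' @examples
#' assign_gender("J. Smith") # "unknown"
#' @export
assign_gender <- function(name, lookup = default_gender_lookup(),
                          min_confidence = 0.8) {
  stopifnot(all(nzchar(name)))
  given <- vapply(name, normalize_given_name, character(1), USE.NAMES = FALSE)
  idx <- match(given, lookup$name)
  label <- lookup$label[idx]
  label[is.na(idx) | is.na(given)] <- "unknown"
  ok <- !is.na(idx) & lookup$confidence[idx] >= min_confidence
  label[!is.na(idx) & !ok] <- "unknown"
  label
}

#' Authorship profiles for every trial in a corpus
#'
#' For each trial: designated sex/gender of first and last author (a single
#' author holds both positions), the leading-woman indicator (woman/female in
#' first and/or last position), the share of women among gender-resolved
#' authors, and the unresolved count. Trials whose authors are all
#' unresolved get `share_women_authors = NA` and are flagged `all_unknown`.
#'
#' @param corpus A `trial_corpus` (or bare trials tibble).
#' @param lookup Name-gender lookup tibble.
#' @param min_confidence Lookup confidence threshold.
#' @return Tibble: `trial_id`, `first_is_woman`, `last_is_woman` (logical,
#'   `NA` = unknown), `leading_woman`, `men_led`, `share_women_authors`,
#'   `n_authors`, `n_unknown`, `all_unknown`.
#' @export
profile_corpus <- function(corpus, lookup = default_gender_lookup(),
                           min_confidence = 0.8) {
  trials <- if (inherits(corpus, "trial_corpus")) corpus$trials else corpus
  if (nrow(trials) == 0)
    abort("corpus has no trials")
  flat <- tidyr::unnest(select(trials, "trial_id", "authors"),
                        "authors")
  flat$label <- assign_gender(flat$full_name, lookup, min_confidence)
  flat$is_woman <- ifelse(flat$label == "unknown", NA,
                          flat$label == "woman_female")
  tri <- function(x) { # collapse a position's labels to one tri-state
    if (!length(x)) NA else x[1]
  }
  prof <- flat %>%
    group_by(.data$trial_id) %>%
    summarise(
      single = dplyr::n() == 1L,
      first_is_woman = tri(.data$is_woman[.data$position == "first"]),
      last_is_woman = if (dplyr::n() == 1L)
        tri(.data$is_woman[.data$position == "first"])
      else tri(.data$is_woman[.data$position == "last"]),
      share_women_authors = if (all(is.na(.data$is_woman))) NA_real_
        else mean(.data$is_woman, na.rm = TRUE),
      n_authors = dplyr::n(),
      n_unknown = sum(is.na(.data$is_woman)),
      .groups = "drop")
  prof <- mutate(prof,
    leading_woman = (!is.na(.data$first_is_woman) & .data$first_is_woman) |
      (!is.na(.data$last_is_woman) & .data$last_is_woman),
    men_led = (!is.na(.data$first_is_woman) & !.data$first_is_woman) &
      (!is.na(.data$last_is_woman) & !.data$last_is_woman),
    all_unknown = .data$n_unknown == .data$n_authors)
  # restore corpus order
  prof <- prof[match(trials$trial_id, prof$trial_id), ]
  select(prof, "trial_id", "first_is_woman", "last_is_woman",
         "leading_woman", "men_led", "share_women_authors", "n_authors",
         "n_unknown", "all_unknown")
}

#' Authorship profile of a single trial
#'
#' @param trial One-row trials tibble (with nested `authors`).
#' @param lookup Name-gender lookup tibble.
#' @param min_confidence Lookup confidence threshold.
#' @return One-row profile tibble (see [profile_corpus()]).
#' @export
profile_trial <- function(trial, lookup = default_gender_lookup(),
                          min_confidence = 0.8) {
  stopifnot(nrow(trial) == 1)
  profile_corpus(trial, lookup, min_confidence)
}

# synthetic given-name pools used by the generator and the packaged lookup
woman_name_pool <- function() {
  c("Anna", "Maria", "Elena", "Sofia", "Laura", "Julia", "Clara", "Nina",
    "Irene", "Paula", "Greta", "Hanna", "Alice", "Emma", "Lucia", "Marta",
    "Sara", "Vera", "Ines", "Nora", "Aisha", "Fatima", "Mei", "Yuki",
    "Priya", "Ananya", "Zanele", "Amara", "Ingrid", "Astrid", "Camille",
    "Chloe", "Isabel", "Beatriz", "Renata", "Valentina", "Olga", "Katarina",
    "Eszter", "Ioanna")
}

man_name_pool <- function() {
  c("James", "Peter", "Thomas", "Henrik", "Lukas", "Marco", "Pablo",
    "Andres", "Viktor", "Ivan", "Omar", "Karim", "Hiroshi", "Kenji", "Wei",
    "Jun", "Arjun", "Rahul", "Kwame", "Tariq", "Lars", "Sven", "Pierre",
    "Louis", "Miguel", "Rafael", "Stefan", "Milan", "Janos", "Nikos",
    "David", "Martin", "Paul", "Simon", "Felix", "Oscar", "Hugo", "Leon",
    "Adam", "Georg")
}
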