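# fixtures built in code, plus independent brute-force oracles

make_authors <- function(names, positions = NULL) {
  if (is.null(positions)) {
    n <- length(names)
    positions <- if (n == 1) "first"
                 else c("first", rep("interior", n - 2), "last")
  }
  tibble::tibble(full_name = names, position = positions)
}

make_trial <- function(trial_id = "NCT00000001", pub_year = 2020L,
                       pub_month = 6L, entity = "Stroke",
                       hf_subtype = NA_character_, n_women = 40L,
                       n_men = 60L,
                       authors = make_authors(c("Anna Smith", "Peter Chen")),
                       countries = rep("USA", nrow(authors))) {
  tibble::tibble(trial_id = trial_id, pub_year = pub_year,
                 pub_month = pub_month, entity = entity,
                 hf_subtype = hf_subtype, n_women = n_women, n_men = n_men,
                 authors = list(authors), countries = list(countries))
}

make_test_corpus <- function() {
  trials <- dplyr::bind_rows(
    make_trial("NCT00000001", 2019L, 3L, "Stroke", n_women = 45L,
               n_men = 55L,
               authors = make_authors(c("Anna Smith", "Peter Chen",
                                        "Maria Rossi")),
               countries = c("DEU", "CHE", "CHE")),
    make_trial("NCT00000002", 2021L, 11L, "HeartFailure",
               hf_subtype = "HFrEF", n_women = 21L, n_men = 79L,
               authors = make_authors(c("James Okafor", "Laura Berg")),
               countries = c("USA", "CAN")),
    make_trial("NCT00000003", 2023L, 7L, "IschemicHeartDisease",
               n_women = 30L, n_men = 90L,
               authors = make_authors("Sara Novak"),
               countries = "JPN"))
  articles <- tibble::tibble(
    trial_id = c("NCT00000001", "NCT00000002"),
    title = c("A trial in women", "A trial"),
    abstract = c("Sex was considered.", "No mention."),
    methods = c("Baseline characteristics by sex are in Table 1.",
                "Standard methods."),
    results = c("Outcomes were consistent in subgroup analyses by sex.",
                "The outcome occurred."),
    discussion = c("Women were underrepresented.", "More work is needed."),
    supplementary = c("", ""),
    has_demographics_table_sex = c(TRUE, FALSE),
    reports_adverse_events = c(TRUE, FALSE))
  new_corpus(trials, articles, provenance = "test fixture")
}

make_article <- function(trial_id = "NCT00000001", title = "", abstract = "",
                         methods = "", results = "", discussion = "",
                         supplementary = "",
                         has_demographics_table_sex = FALSE,
                         reports_adverse_events = FALSE) {
  tibble::tibble(trial_id = trial_id, title = title, abstract = abstract,
                 methods = methods, results = results,
                 discussion = discussion, supplementary = supplementary,
                 has_demographics_table_sex = has_demographics_table_sex,
                 reports_adverse_events = reports_adverse_events)
}

# brute-force whole-word matcher: split on non-word characters and compare
# tokens; independent of the regex path in the package
oracle_matched_terms <- function(text, terms) {
  tokens <- strsplit(tolower(text), "[^a-z0-9_]+")[[1]]
  sort(unique(terms[terms %in% tokens]))
}

trap_vocabulary <- function() {
  c("women", "men", "male", "female", "sex", "gender", "subgroup",
    "adverse", "management", "regimen", "semen", "acumen", "maleate",
    "treatment", "outcome", "placebo", "femoral", "adversely", "xmen",
    "omen", "females")
}

random_trap_string <- function(n_tokens = 8) {
  toks <- sample(trap_vocabulary(), n_tokens, replace = TRUE)
  seps <- sample(c(" ", ", ", "-", "/", ". ", "; "), n_tokens - 1,
                 replace = TRUE)
  paste0(paste0(toks[-n_tokens], seps, collapse = ""), toks[n_tokens])
}

# exhaustive Mann-Whitney oracle: enumerate every assignment of the pooled
# ranks to group A via combn
oracle_mann_whitney <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  ranks <- rank(c(a, b))
  r_obs <- sum(ranks[seq_len(n_a)])
  u_obs <- r_obs - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  sums <- apply(combos, 2, function(idx) sum(ranks[idx]))
  p_low <- mean(sums <= r_obs)
  p_high <- mean(sums >= r_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_low, p_high)))
}

oracle_chi_square <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
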