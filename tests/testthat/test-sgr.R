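test_that("find_terms matches whole words only, case-insensitively", {
  hits <- find_terms("Women and men differed by sex")
  expect_setequal(hits$term, c("women", "men", "sex"))
  hits <- find_terms("management of adverse-event treatment")
  expect_equal(hits$term, "adverse")
  expect_equal(nrow(find_terms("")), 0L)
  # slash and hyphen act as boundaries
  expect_setequal(find_terms("sex/gender-stratified")$term,
                  c("sex", "gender"))
  # "male" never fires inside "female", "men" never inside "women"
  expect_equal(find_terms("female females")$term, "female")
  expect_false("men" %in% find_terms("women acumen management")$term)
})

test_that("find_terms agrees with a brute-force tokenizer on trap strings", {
  lex <- default_lexicon()
  set.seed(31)
  for (i in 1:300) {
    s <- random_trap_string()
    expect_equal(sort(unique(find_terms(s, lex)$term)),
                 oracle_matched_terms(s, lex$terms), info = s)
  }
})

test_that("score_article assigns section flags per the scoring rules", {
  # endpoint: sex/gender term and a subgroup locator in one sentence
  a <- make_article(results = paste("The effect was consistent in subgroup",
                                    "analyses by sex."))
  s <- score_article(a)
  expect_true(s$endpoint_flag)
  expect_true(s$results_text_flag) # same term also counts as in-text mention
  # locator in a different sentence does not qualify
  a <- make_article(results = "Subgroup analyses were done. Sex was noted.")
  expect_false(score_article(a)$endpoint_flag)
  # demographics-only article scores core_sum 1
  a <- make_article(has_demographics_table_sex = TRUE)
  s <- score_article(a)
  expect_equal(s$core_sum, 1L)
  expect_false(s$high_sgr)
  expect_equal(s$demographics_source, "curated")
  # heuristic fallback: sex term in a baseline-characteristics sentence
  a <- make_article(methods = "Baseline characteristics by sex in Table 1.")
  s <- score_article(a)
  expect_true(s$demographics_flag)
  expect_equal(s$demographics_source, "heuristic")
  # four qualifying sections saturate the score
  a <- make_article(
    methods = "Randomized design.",
    results = paste("Sex was recorded.",
                    "Effects were consistent in subgroup analyses by sex."),
    discussion = "Women were underrepresented.",
    has_demographics_table_sex = TRUE)
  s <- score_article(a)
  expect_equal(s$core_sum, 4L)
  expect_true(s$high_sgr)
  # title/abstract flags do not feed the core sum
  a <- make_article(title = "Sex differences", abstract = "Women enrolled.")
  s <- score_article(a)
  expect_true(s$title_flag)
  expect_true(s$abstract_flag)
  expect_equal(s$core_sum, 0L)
  # locator tokens alone are not sex/gender mentions
  a <- make_article(results = "Subgroup and adverse analyses were done.")
  s <- score_article(a)
  expect_false(s$results_text_flag)
  expect_equal(s$core_sum, 0L)
})

test_that("adverse stratification is conditional on adverse-event reporting", {
  a <- make_article(results = "Adverse events were similar in women and men.",
                    reports_adverse_events = TRUE)
  expect_true(score_article(a)$adverse_stratified_flag)
  a$reports_adverse_events <- FALSE
  expect_true(is.na(score_article(a)$adverse_stratified_flag))
  a <- make_article(results = "Adverse events occurred. Women enrolled.",
                    reports_adverse_events = TRUE)
  expect_false(score_article(a)$adverse_stratified_flag)
})

test_that("adding text to a section never turns a true flag false", {
  set.seed(32)
  base <- make_article(
    results = "Sex effects were consistent in subgroup analyses.",
    discussion = "Women were underrepresented.",
    has_demographics_table_sex = TRUE, reports_adverse_events = TRUE)
  s0 <- score_article(base)
  flags <- c("title_flag", "abstract_flag", "demographics_flag",
             "results_text_flag", "endpoint_flag", "discussion_flag")
  for (i in 1:20) {
    extra <- random_trap_string()
    grown <- base
    for (sec in c("title", "abstract", "methods", "results", "discussion",
                  "supplementary"))
      grown[[sec]] <- paste0(grown[[sec]], " ", extra, ".")
    s1 <- score_article(grown)
    for (f in flags)
      if (isTRUE(s0[[f]])) expect_true(s1[[f]], info = f)
  }
})

test_that("corpus_sgr_summary computes group shares and restricted denominators", {
  scores <- tibble::tibble(
    trial_id = sprintf("NCT%08d", 1:10),
    title_flag = FALSE, abstract_flag = FALSE,
    demographics_flag = TRUE, demographics_source = "curated",
    results_text_flag = rep(c(TRUE, FALSE), 5),
    endpoint_flag = FALSE, discussion_flag = FALSE,
    adverse_stratified_flag = c(TRUE, FALSE, rep(NA, 8)),
    reports_adverse_events = c(TRUE, TRUE, rep(FALSE, 8)),
    core_sum = rep(c(2L, 1L), 5),
    high_sgr = c(rep(TRUE, 4), rep(FALSE, 6)),
    pub_year = rep(c(2019L, 2022L), each = 5),
    entity = "Stroke")
  s <- corpus_sgr_summary(scores, "none")
  expect_equal(s$share_high_sgr, 0.4)
  expect_equal(s$share_adverse_stratified, 0.5) # 1 of 2 AE-reporting
  expect_equal(s$n_adverse_reporting, 2L)
  expect_equal(s$share_sum_1 + s$share_sum_2, 1)
  by_year <- corpus_sgr_summary(scores, "year")
  expect_equal(nrow(by_year), 2L)
  expect_equal(sum(by_year$n), 10L)
  # degenerate: all articles at the maximum sum
  scores$core_sum <- 4L
  s <- corpus_sgr_summary(scores, "none")
  expect_equal(s$share_sum_4, 1)
})

test_that("lexicon YAML override replaces the term list", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("terms:", "  - sex", "  - gender", "  - subgroup"), path)
  lex <- read_lexicon(path)
  expect_setequal(lex$terms, c("sex", "gender", "subgroup"))
  expect_setequal(lex$sex_gender_terms, c("sex", "gender"))
  expect_equal(find_terms("women and sex", lex)$term, "sex")
})
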