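test_that("the generator is deterministic given a seed and honours n_trials = 0", {
  empty <- generate_corpus(simulation_config(n_trials = 0, seed = 1))
  expect_equal(nrow(empty$corpus$trials), 0L)
  cfg <- simulation_config(n_trials = 40, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_corpus(a$corpus, file.path(d1, "c.csv"), "csv",
               articles_path = file.path(d1, "a.json"))
  write_corpus(b$corpus, file.path(d2, "c.csv"), "csv",
               articles_path = file.path(d2, "a.json"))
  expect_equal(unname(tools::md5sum(file.path(d1, c("c.csv", "a.json")))),
               unname(tools::md5sum(file.path(d2, c("c.csv", "a.json")))))
  expect_equal(a$truth, b$truth)
  # different seeds differ
  c2 <- generate_corpus(simulation_config(n_trials = 40, seed = 124))
  expect_false(identical(a$truth, c2$truth))
})

test_that("seed is mandatory and infeasible share shifts are rejected", {
  expect_error(simulation_config(n_trials = 10), "seed")
  expect_error(
    simulation_config(n_trials = 10, seed = 1, delta_share = 0.9),
    "infeasible")
})

test_that("planted keyword sentences trip their own core flag and no other", {
  tmpl <- equitrial:::sgr_templates()
  base <- make_article(title = paste0(tmpl$title_base, "."),
                       abstract = tmpl$filler_abstract,
                       methods = tmpl$filler_methods,
                       results = tmpl$filler_results,
                       discussion = tmpl$filler_discussion,
                       reports_adverse_events = TRUE)
  core <- c("demographics_flag", "results_text_flag", "endpoint_flag",
            "discussion_flag")
  s0 <- score_article(base)
  expect_true(all(!unlist(s0[core]))) # fillers trip nothing
  plant <- list(
    demographics_flag = function(a) {
      a$has_demographics_table_sex <- TRUE; a },
    results_text_flag = function(a) {
      a$results <- paste0(a$results, tmpl$results_flagged); a },
    endpoint_flag = function(a) {
      a$supplementary <- tmpl$endpoint_flagged; a },
    discussion_flag = function(a) {
      a$discussion <- paste0(a$discussion, tmpl$discussion_flagged); a })
  for (target in core) {
    s <- score_article(plant[[target]](base))
    for (f in core)
      expect_equal(unname(unlist(s[f])), f == target,
                   info = paste(target, "->", f))
  }
  # adverse template trips the adverse flag but no core flag
  a <- base
  a$supplementary <- trimws(tmpl$adverse_flagged)
  s <- score_article(a)
  expect_true(s$adverse_stratified_flag)
  expect_true(all(!unlist(s[core])))
})

test_that("generated corpora reproduce configured marginals and planted flags", {
  sim <- generate_corpus(simulation_config(n_trials = 5000, seed = 77))
  cfg <- sim$config
  # entity marginal: goodness-of-fit against configured probabilities
  obs <- table(factor(sim$corpus$trials$entity,
                      levels = names(cfg$entity_weights)))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$entity_weights))
  expect_gt(gof$p.value, 0.001)
  # derived (majority-affiliation) region marginal
  regions <- vapply(sim$corpus$trials$countries, majority_region,
                    character(1))
  obs <- table(factor(regions, levels = names(cfg$region_weights)))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$region_weights))
  expect_gt(gof$p.value, 0.001)
  # year marginal
  obs <- table(factor(sim$corpus$trials$pub_year,
                      levels = names(cfg$year_weights)))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$year_weights))
  expect_gt(gof$p.value, 0.001)
  # trial sizes respect the configured band edges
  size <- sim$corpus$trials$n_women + sim$corpus$trials$n_men
  expect_true(all(size >= cfg$size_bounds[1] & size <= cfg$size_bounds[5]))
  # the scanner recovers every planted core flag in the SGR subsample
  scores <- score_corpus(sim$corpus)
  truth <- sim$truth[sim$truth$in_sgr_sample, ]
  truth <- truth[match(scores$trial_id, truth$trial_id), ]
  expect_equal(scores$demographics_flag, truth$demographics_flag)
  expect_equal(scores$results_text_flag, truth$results_text_flag)
  expect_equal(scores$endpoint_flag, truth$endpoint_flag)
  expect_equal(scores$discussion_flag, truth$discussion_flag)
  expect_equal(scores$high_sgr, truth$high_sgr)
})

test_that("with couplings off, women-led and men-led shares agree within 2 SE", {
  diffs <- vapply(1:60, function(i) {
    sim <- generate_corpus(simulation_config(
      n_trials = 120, seed = 9000 + i, delta_share = 0, or_sgr = 1,
      or_sgr_ppr_above = 1))
    share <- trial_women_share(sim$corpus$trials)
    lw <- sim$truth$leading_woman
    mean(share[lw]) - mean(share[!lw])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("emit_fixture_suite writes a deterministic file set", {
  d <- tempfile()
  paths <- emit_fixture_suite(d)
  expect_length(paths, 5L) # corpus, articles, prevalence, lookup + manifest
  expect_true(all(file.exists(paths)))
  sums1 <- tools::md5sum(paths[names(paths) != "manifest"])
  paths2 <- emit_fixture_suite(d) # rerun in place
  expect_equal(tools::md5sum(paths2[names(paths2) != "manifest"]), sums1)
  # the fixture round-trips through the loader
  corpus <- load_corpus(paths[["corpus"]], "csv",
                        articles_path = paths[["articles"]])
  expect_equal(nrow(corpus$trials), 60L)
  # unusable output location errors
  blocker <- tempfile()
  writeLines("x", blocker)
  expect_error(emit_fixture_suite(file.path(blocker, "sub")), "cannot create")
})
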