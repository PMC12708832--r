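# Publication-style summary table and pipeline orchestration commands.

pct_block <- function(dimension, key, n_women, n_total, grand_studies) {
  agg <- tibble(key = key, w = n_women, t = n_total) %>%
    group_by(.data$key) %>%
    summarise(n_studies = dplyr::n(), n_women = sum(.data$w),
              n_total = sum(.data$t), .groups = "drop")
  tibble(dimension = dimension, level = as.character(agg$key),
         n_studies = agg$n_studies,
         pct_studies = round_half_up(100 * agg$n_studies / grand_studies, 1),
         n_women = agg$n_women, n_total = agg$n_total,
         pct_women = pct_women(agg$n_women, agg$n_total))
}

#' Build a publication-style participation summary table
#'
#' Counts of studies and of women/total participants, with the women
#' percentage rounded half-up to one decimal, grouped exactly as the
#' published corpus description: total, publication year, disease entity,
#' World Bank region, trial-size quartile, leading-author group and (when
#' SGR scores are supplied) SGR below/at-least three of four sections.
#'
#' @param corpus A `trial_corpus`.
#' @param ppr_results Output of [ppr_for_corpus()] (supplies regions).
#' @param sgr_scores Optional output of [score_corpus()].
#' @param profiles Output of [profile_corpus()].
#' @param quartile_bounds Optional c(q1, q2, q3) trial-size boundaries; by
#'   default type-7 quantiles computed from the corpus. Supply published
#'   bounds (e.g. 72/182/617) for replication-style runs.
#' @return Tibble: `dimension`, `level`, `n_studies`, `pct_studies`,
#'   `n_women`, `n_total`, `pct_women`.
#' @export
build_table1 <- function(corpus, ppr_results, sgr_scores = NULL,
                         profiles = NULL, quartile_bounds = NULL) {
  trials <- corpus$trials
  nw <- trials$n_women
  nt <- trials$n_women + trials$n_men
  gn <- nrow(trials)
  out <- list(pct_block("total", rep("Total", gn), nw, nt, gn))
  out <- c(out, list(pct_block("year", trials$pub_year, nw, nt, gn)))
  out <- c(out, list(pct_block("entity", trials$entity, nw, nt, gn)))
  regions <- ppr_results$region[match(trials$trial_id, ppr_results$trial_id)]
  out <- c(out, list(pct_block("region", regions, nw, nt, gn)))

  if (is.null(quartile_bounds))
    quartile_bounds <- unname(quantile(nt, c(0.25, 0.5, 0.75), type = 7))
  qb <- quartile_bounds
  qlab <- c(sprintf("First (<= %g)", qb[1]),
            sprintf("Second (%g < x <= %g)", qb[1], qb[2]),
            sprintf("Third (%g < x <= %g)", qb[2], qb[3]),
            sprintf("Fourth (> %g)", qb[3]))
  quartile <- qlab[findInterval(nt, c(-Inf, qb), left.open = TRUE)]
  blk <- pct_block("size_quartile", quartile, nw, nt, gn)
  blk <- blk[match(qlab[qlab %in% blk$level], blk$level), ]
  out <- c(out, list(blk))

  if (!is.null(profiles)) {
    lead <- ifelse(profiles$leading_woman[match(trials$trial_id,
                                                profiles$trial_id)],
                   "Yes", "No")
    out <- c(out, list(pct_block("leading_author", lead, nw, nt, gn)))
  }
  if (!is.null(sgr_scores) && nrow(sgr_scores) > 0) {
    idx <- match(sgr_scores$trial_id, trials$trial_id)
    grp <- ifelse(sgr_scores$high_sgr, "At least 3 of 4", "Less than 3 of 4")
    out <- c(out, list(
      pct_block("sgr_subsample", rep("All", length(idx)), nw[idx], nt[idx],
                gn),
      pct_block("sgr_group", grp, nw[idx], nt[idx], length(idx))))
  } else if (!is.null(sgr_scores)) {
    warn("empty SGR subsample: SGR block omitted")
  }
  bind_rows(out)
}

#' Run the full analysis pipeline on a corpus
#'
#' Convenience wrapper chaining region derivation, PPR computation, SGR
#' scoring (when article texts are present), authorship profiling, the
#' association suite and the summary table.
#'
#' @param corpus A `trial_corpus`.
#' @param prevalence Prevalence table.
#' @param lookup Name-gender lookup.
#' @param lexicon Keyword lexicon.
#' @param quartile_bounds Passed to [build_table1()].
#' @return List: `ppr`, `sgr`, `profiles`, `associations`, `table1`.
#' @export
run_pipeline <- function(corpus, prevalence = default_prevalence_table(),
                         lookup = default_gender_lookup(),
                         lexicon = default_lexicon(),
                         quartile_bounds = NULL) {
  ppr <- ppr_for_corpus(corpus, prevalence)
  sgr <- if (!is.null(corpus$articles)) score_corpus(corpus, lexicon)
         else NULL
  profiles <- profile_corpus(corpus, lookup)
  assoc <- run_association_suite(corpus, ppr, sgr, profiles)
  tab1 <- build_table1(corpus, ppr, sgr, profiles, quartile_bounds)
  list(ppr = ppr, sgr = sgr, profiles = profiles, associations = assoc,
       table1 = tab1)
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Pipeline commands
#'
#' Thin command wrappers over the package functions, used by the
#' `equitrial` command-line script but callable directly. Each stage reads
#' and writes the documented file formats so stages can run independently
#' or chained.
#'
#' `cmd_simulate` generates a synthetic corpus and writes corpus CSV,
#' article JSON, prevalence CSV, lookup CSV and the ground truth.
#' `cmd_score` scores SGR for a corpus and writes one row per article.
#' `cmd_associate` runs the association suite and writes JSON results.
#' `cmd_report` writes the summary table, the per-trial PPR/SGR/profile
#' table and the association JSON.
#'
#' @param n_trials,seed,config Simulation size, seed, optional YAML config
#'   path.
#' @param outdir Output directory.
#' @param corpus_path,articles_path Corpus CSV and article JSON paths.
#' @param prevalence_path,lookup_path,lexicon_path Optional overrides of the
#'   packaged defaults.
#' @param out Output file path.
#' @param verbose Log stage counts to stderr.
#' @return Invisibly, the written file path(s).
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(n_trials, seed, outdir, config = NULL,
                         verbose = FALSE) {
  cfg <- if (is.null(config))
    simulation_config(n_trials = n_trials, seed = seed)
  else read_simulation_config(config, n_trials = n_trials, seed = seed)
  sim <- generate_corpus(cfg)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(corpus = file.path(outdir, "corpus.csv"),
             articles = file.path(outdir, "corpus_articles.json"),
             prevalence = file.path(outdir, "prevalence.csv"),
             lookup = file.path(outdir, "gender_lookup.csv"),
             truth = file.path(outdir, "truth.csv"))
  write_corpus(sim$corpus, paths[["corpus"]], "csv",
               articles_path = paths[["articles"]])
  write.csv(cfg$prevalence, paths[["prevalence"]], row.names = FALSE)
  write.csv(default_gender_lookup(), paths[["lookup"]], row.names = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  log_msg(verbose, "simulated %d trials (%d with full text) -> %s",
          nrow(sim$corpus$trials),
          if (is.null(sim$corpus$articles)) 0L else nrow(sim$corpus$articles),
          outdir)
  invisible(paths)
}

load_inputs <- function(corpus_path, articles_path, prevalence_path = NULL,
                        lookup_path = NULL, lexicon_path = NULL) {
  corpus <- load_corpus(corpus_path, "csv", articles_path = articles_path)
  list(corpus = corpus,
       prevalence = if (is.null(prevalence_path)) default_prevalence_table()
                    else read_prevalence_table(prevalence_path),
       lookup = if (is.null(lookup_path)) default_gender_lookup()
                else read_gender_lookup(lookup_path),
       lexicon = if (is.null(lexicon_path)) default_lexicon()
                 else read_lexicon(lexicon_path))
}

#' @rdname pipeline_commands
#' @export
cmd_score <- function(corpus_path, articles_path, out, lexicon_path = NULL,
                      verbose = FALSE) {
  inp <- load_inputs(corpus_path, articles_path, lexicon_path = lexicon_path)
  scores <- score_corpus(inp$corpus, inp$lexicon)
  write.csv(scores, out, row.names = FALSE)
  log_msg(verbose, "scored %d articles -> %s", nrow(scores), out)
  invisible(out)
}

#' @rdname pipeline_commands
#' @export
cmd_associate <- function(corpus_path, articles_path, out,
                          prevalence_path = NULL, lookup_path = NULL,
                          lexicon_path = NULL, verbose = FALSE) {
  inp <- load_inputs(corpus_path, articles_path, prevalence_path,
                     lookup_path, lexicon_path)
  res <- run_pipeline(inp$corpus, inp$prevalence, inp$lookup, inp$lexicon)
  write_association_results(res$associations, out)
  log_msg(verbose, "association suite on %d trials -> %s",
          nrow(inp$corpus$trials), out)
  invisible(out)
}

#' @rdname pipeline_commands
#' @export
cmd_report <- function(corpus_path, articles_path, outdir,
                       prevalence_path = NULL, lookup_path = NULL,
                       lexicon_path = NULL, verbose = FALSE) {
  inp <- load_inputs(corpus_path, articles_path, prevalence_path,
                     lookup_path, lexicon_path)
  res <- run_pipeline(inp$corpus, inp$prevalence, inp$lookup, inp$lexicon)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(table1 = file.path(outdir, "table1.csv"),
             per_trial = file.path(outdir, "per_trial.csv"),
             associations = file.path(outdir, "associations.json"))
  write.csv(res$table1, paths[["table1"]], row.names = FALSE)
  per_trial <- res$ppr %>%
    left_join(res$profiles, by = "trial_id") %>%
    left_join(if (is.null(res$sgr)) tibble(trial_id = character(0))
              else select(res$sgr, -"pub_year", -"entity"),
              by = "trial_id")
  write.csv(per_trial, paths[["per_trial"]], row.names = FALSE)
  write_association_results(res$associations, paths[["associations"]])
  log_msg(verbose, "report on %d trials -> %s", nrow(inp$corpus$trials),
          outdir)
  invisible(paths)
}
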