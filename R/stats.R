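# Corpus-level statistics: distribution-free median CIs, Pearson time
# trends, Mann-Whitney rank tests, 2x2 chi-square, and logistic-regression
# odds ratios, plus the orchestrated association suite.

#' Median with 95% confidence interval
#'
#' `order_statistic` (default) uses the distribution-free binomial rank
#' interval: with sorted values x(1..n), the interval \[x(l), x(n+1-l)\] where
#' l is the largest rank with P(Binom(n, 1/2) < l) <= alpha/2, giving at
#' least the nominal coverage. `bootstrap` uses the percentile interval over
#' B = 2000 resamples and requires a seed.
#'
#' @param values Numeric vector, n >= 1.
#' @param method `"order_statistic"` or `"bootstrap"`.
#' @param confidence Coverage level (default 0.95).
#' @param seed Integer seed (bootstrap only; mandatory there).
#' @param B Bootstrap resamples (default 2000).
#' @return List: `median`, `ci_low`, `ci_high`, `method`, `n` (and `seed`).
#' @examples
#' median_ci(c(1, 2, 3, 4, 5))
#' @export
median_ci <- function(values, method = c("order_statistic", "bootstrap"),
                      confidence = 0.95, seed = NULL, B = 2000) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) abort("median_ci needs at least one value")
  med <- median(values)
  alpha <- 1 - confidence
  if (method == "order_statistic") {
    x <- sort(values)
    l <- qbinom(alpha / 2, n, 0.5)
    if (l < 1) {
      ci <- c(x[1], x[n])
    } else {
      ci <- c(x[l], x[n + 1 - l])
    }
    list(median = med, ci_low = ci[1], ci_high = ci[2],
         method = method, n = n)
  } else {
    if (is.null(seed)) abort("bootstrap median_ci requires a seed")
    meds <- withr_seed(seed, {
      vapply(seq_len(B), function(i)
        median(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    })
    ci <- unname(quantile(meds, c(alpha / 2, 1 - alpha / 2), type = 7))
    list(median = med, ci_low = min(ci[1], med), ci_high = max(ci[2], med),
         method = method, n = n, seed = seed)
  }
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pearson trend of a series against time
#'
#' Pearson correlation (two-sided p from the t distribution on n-2 df) plus
#' the least-squares slope and intercept.
#'
#' @param y Numeric response (e.g. per-trial shares or PPRs).
#' @param time Numeric time axis (decimal years).
#' @return List: `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pearson_trend <- function(y, time) {
  keep <- !is.na(y) & !is.na(time)
  y <- y[keep]; time <- time[keep]
  n <- length(y)
  if (n < 3) abort("pearson_trend needs n >= 3")
  if (stats::sd(y) == 0 || stats::sd(time) == 0)
    abort("zero variance in trend input")
  ct <- cor.test(time, y, method = "pearson", alternative = "two.sided")
  fit <- lm(y ~ time)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = n)
}

# distribution of the rank sum of samples of size m from the given midranks,
# by subset-sum dynamic programming over doubled (integer) ranks
rank_sum_distribution <- function(ranks2, m) {
  total <- sum(ranks2)
  # dp[[k]][s+1] = number of k-subsets with doubled-rank sum s
  dp <- vector("list", m + 1)
  dp[[1]] <- c(1, numeric(total))
  for (k in seq_len(m)) dp[[k + 1]] <- numeric(total + 1)
  for (r in ranks2) {
    for (k in rev(seq_len(m))) {
      shifted <- c(numeric(r), dp[[k]][seq_len(total + 1 - r)])
      dp[[k + 1]] <- dp[[k + 1]] + shifted
    }
  }
  dp[[m + 1]] # counts over doubled rank sums 0..total
}

#' Mann-Whitney U test
#'
#' U for the first sample from rank sums with midranks for ties. For
#' combined sizes up to 20 the two-sided p-value comes from exact
#' enumeration of the rank-sum distribution (ties included); larger samples
#' use the tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Numeric samples.
#' @return List: `U`, `p_value`, `method`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) abort("both samples must be non-empty")
  ranks <- rank(c(a, b))
  r_a <- sum(ranks[seq_len(n_a)])
  u <- r_a - n_a * (n_a + 1) / 2
  if (n_a + n_b <= 20) {
    ranks2 <- as.integer(round(2 * ranks))
    counts <- rank_sum_distribution(ranks2, n_a)
    totals <- choose(n_a + n_b, n_a)
    sums2 <- seq_along(counts) - 1
    obs2 <- as.integer(round(2 * r_a))
    p_low <- sum(counts[sums2 <= obs2]) / totals
    p_high <- sum(counts[sums2 >= obs2]) / totals
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    n <- n_a + n_b
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    mu <- n_a * n_b / 2
    sigma <- sqrt(n_a * n_b / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sigma
      z <- max(z, 0)
      p <- 2 * pnorm(z, lower.tail = FALSE)
    }
    method <- "normal_approx"
  }
  list(U = u, p_value = p, method = method, n_a = n_a, n_b = n_b)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1. Errors on a zero row or column
#' marginal.
#'
#' @param table 2x2 matrix of counts.
#' @return List: `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_2x2(matrix(c(10, 20, 20, 10), 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("chi_square_2x2: zero marginal")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value, df = 1L)
}

#' Logistic-regression odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on one (univariate)
#' or two (multiple) binary predictors; odds ratios with Wald 95%
#' confidence intervals `exp(coef +- 1.96 SE)`.
#'
#' @param outcome Binary (0/1 or logical) outcome vector.
#' @param predictors Named list or data.frame of one or two binary vectors.
#' @return Tibble: `predictor`, `or_value`, `ci_low`, `ci_high`, `p_value`,
#'   `model` (univariate / multiple).
#' @examples
#' x <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
#' y <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
#' logistic_or(y, list(exposure = x)) # OR 6.0
#' @export
logistic_or <- function(outcome, predictors) {
  outcome <- as.numeric(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    abort("degenerate outcome: needs both 0 and 1")
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  stopifnot(length(predictors) %in% 1:2, !is.null(names(predictors)))
  dat <- as.data.frame(lapply(predictors, as.numeric))
  dat$.y <- outcome
  dat <- dat[stats::complete.cases(dat), ]
  for (nm in names(predictors)) {
    if (length(unique(dat[[nm]])) < 2)
      abort(sprintf("degenerate predictor '%s'", nm))
  }
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial()))
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  bad <- !fit$converged | abs(est) > 15 | se > 50
  if (any(bad))
    abort(sprintf("separation or non-convergence for predictor(s): %s",
                  paste(names(est)[bad], collapse = ", ")))
  z <- unname(est / se)
  est_names <- names(est)
  est <- unname(est); se <- unname(se)
  tibble(predictor = est_names,
         or_value = exp(est),
         ci_low = exp(est - 1.96 * se),
         ci_high = exp(est + 1.96 * se),
         p_value = 2 * pnorm(abs(z), lower.tail = FALSE),
         model = if (length(predictors) == 1) "univariate" else "multiple",
         n = nrow(dat))
}

decimal_time <- function(year, month) year + (month - 0.5) / 12

#' Run the corpus-level association suite
#'
#' Joins per-trial PPR results, SGR scores and authorship profiles and
#' reproduces the analysis set: medians with 95% CI for share and PPR,
#' Pearson trends of share and PPR over publication time, Mann-Whitney
#' comparison of PPR between women-led and men-led trials, correlation of
#' the share of women among authors with PPR, chi-square contrasts of high
#' SGR by leading authorship and by PPR category, and the two univariate
#' plus one multiple logistic model of high SGR on leading-woman authorship
#' and optimal PPR. Trials whose leading authorship cannot be resolved are
#' excluded from the women-led vs men-led dichotomy.
#'
#' @param corpus A `trial_corpus`.
#' @param ppr_results Output of [ppr_for_corpus()].
#' @param sgr_scores Output of [score_corpus()] (NULL to skip SGR analyses).
#' @param profiles Output of [profile_corpus()].
#' @return An `association_results` list.
#' @export
run_association_suite <- function(corpus, ppr_results, sgr_scores,
                                  profiles) {
  trials <- corpus$trials
  if (nrow(trials) < 3)
    abort("association suite needs at least 3 trials")
  dat <- trials %>%
    select("trial_id", "pub_year", "pub_month") %>%
    mutate(share = trial_women_share(trials),
           time = decimal_time(.data$pub_year, .data$pub_month)) %>%
    left_join(select(ppr_results, "trial_id", "ppr", "category"),
              by = "trial_id") %>%
    left_join(select(profiles, "trial_id", "leading_woman", "men_led",
                     "share_women_authors"),
              by = "trial_id")
  dat$optimal <- dat$category == "optimal"

  res <- list(
    n_trials = nrow(dat),
    median_share = median_ci(dat$share),
    median_ppr = median_ci(dat$ppr),
    trend_share = pearson_trend(dat$share, dat$time),
    trend_ppr = pearson_trend(dat$ppr, dat$time))

  led <- dat[dat$leading_woman | dat$men_led, ]
  mw <- mann_whitney(led$ppr[led$leading_woman], led$ppr[led$men_led])
  res$mw_ppr_leading <- c(mw, list(
    median_women_led = median(led$ppr[led$leading_woman]),
    median_men_led = median(led$ppr[led$men_led])))

  keep <- !is.na(dat$share_women_authors)
  ct <- cor.test(dat$share_women_authors[keep], dat$ppr[keep])
  res$cor_share_authors_ppr <- list(r = unname(ct$estimate),
                                    p_value = ct$p.value, n = sum(keep))

  if (!is.null(sgr_scores) && nrow(sgr_scores) > 0) {
    sg <- left_join(select(sgr_scores, "trial_id", "high_sgr"),
                    select(dat, "trial_id", "leading_woman", "men_led",
                           "optimal", "category"),
                    by = "trial_id")
    sg_led <- sg[sg$leading_woman | sg$men_led, ]
    res$chisq_sgr_leading <- chi_square_2x2(
      table(sg_led$leading_woman, sg_led$high_sgr))
    res$chisq_sgr_optimal <- chi_square_2x2(
      table(sg$optimal, sg$high_sgr))
    ao <- sg[sg$category %in% c("above", "optimal"), ]
    res$chisq_sgr_above_vs_optimal <- if (length(unique(ao$category)) == 2)
      chi_square_2x2(table(ao$category == "above", ao$high_sgr)) else NULL

    uni_lead <- logistic_or(sg_led$high_sgr,
                            list(leading_woman = sg_led$leading_woman))
    uni_opt <- logistic_or(sg$high_sgr, list(optimal_ppr = sg$optimal))
    multi <- logistic_or(sg_led$high_sgr,
                         list(leading_woman = sg_led$leading_woman,
                              optimal_ppr = sg_led$optimal))
    res$or_table <- bind_rows(uni_lead, uni_opt, multi)
    res$n_sgr <- nrow(sg)
  }
  structure(res, class = "association_results")
}

#' @export
print.association_results <- function(x, ...) {
  cat(sprintf("<association_results> %d trials\n", x$n_trials))
  cat(sprintf("  median share %.3f [%.3f, %.3f]; median PPR %.2f [%.2f, %.2f]\n",
              x$median_share$median, x$median_share$ci_low,
              x$median_share$ci_high, x$median_ppr$median,
              x$median_ppr$ci_low, x$median_ppr$ci_high))
  cat(sprintf("  share trend r = %.3f (p = %.3g); PPR trend r = %.3f (p = %.3g)\n",
              x$trend_share$r, x$trend_share$p_value,
              x$trend_ppr$r, x$trend_ppr$p_value))
  cat(sprintf("  Mann-Whitney PPR women-led vs men-led: U = %.1f, p = %.3g\n",
              x$mw_ppr_leading$U, x$mw_ppr_leading$p_value))
  if (!is.null(x$or_table)) {
    cat("  odds ratios for high SGR:\n")
    print(as.data.frame(x$or_table), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize association results to JSON
#'
#' @param results An `association_results` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_association_results <- function(results, path) {
  out <- unclass(results)
  if (!is.null(out$or_table)) out$or_table <- as.data.frame(out$or_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
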