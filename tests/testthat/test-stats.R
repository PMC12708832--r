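test_that("median_ci returns the sample median with a rank-based interval", {
  r <- median_ci(c(1, 2, 3, 4, 5))
  expect_equal(r$median, 3)
  expect_true(r$ci_low <= r$median && r$median <= r$ci_high)
  r <- median_ci(rep(7, 12))
  expect_equal(r$median, 7)
  expect_equal(c(r$ci_low, r$ci_high), c(7, 7))
  expect_error(median_ci(numeric(0)), "at least one")
})

test_that("order-statistic interval equals brute-force binomial rank bounds", {
  set.seed(51)
  x <- runif(100)
  r <- median_ci(x)
  n <- length(x)
  # oracle: scan all ranks for the largest l with P(Binom < l) <= alpha/2
  lower_tail <- pbinom(0:n - 1, n, 0.5)
  l <- max(which(lower_tail <= 0.025)) # index into 0..n -> l = value
  l <- (0:n)[l]
  xs <- sort(x)
  expect_equal(r$ci_low, xs[l])
  expect_equal(r$ci_high, xs[n + 1 - l])
})

test_that("order-statistic interval attains nominal coverage on skewed data", {
  set.seed(52)
  true_med <- log(2)
  hits <- replicate(1000, {
    r <- median_ci(rexp(50))
    r$ci_low <= true_med && true_med <= r$ci_high
  })
  expect_gte(mean(hits), 0.95)
})

test_that("bootstrap interval requires a seed and is reproducible", {
  x <- rexp(40)
  expect_error(median_ci(x, method = "bootstrap"), "seed")
  r1 <- median_ci(x, method = "bootstrap", seed = 99)
  r2 <- median_ci(x, method = "bootstrap", seed = 99)
  expect_equal(r1, r2)
  expect_true(r1$ci_low <= r1$median && r1$median <= r1$ci_high)
})

test_that("pearson_trend reproduces the closed-form correlation", {
  t <- seq(2018, 2024, length.out = 20)
  r <- pearson_trend(0.3 + 0.02 * t, t)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 0.02, tolerance = 1e-9)
  expect_error(pearson_trend(rep(0.4, 10), seq_len(10)), "zero variance")
  expect_error(pearson_trend(c(1, 2), c(1, 2)), "n >= 3")
  set.seed(53)
  y <- runif(10); tt <- runif(10)
  r <- pearson_trend(y, tt)
  # oracle: direct covariance / sd formula and t-distribution p
  r_oracle <- sum((y - mean(y)) * (tt - mean(tt))) /
    sqrt(sum((y - mean(y))^2) * sum((tt - mean(tt))^2))
  tstat <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(abs(tstat), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(sign(r$r), sign(r$slope))
})

test_that("mann_whitney handles separation, identity and small-sample exactness", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  r <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p_value, 1)
  o <- oracle_mann_whitney(c(1, 3, 5), c(2, 4))
  r <- mann_whitney(c(1, 3, 5), c(2, 4))
  expect_equal(r$U, o$U)
  expect_equal(r$p_value, o$p_value)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  # large samples agree with the tie-corrected normal approximation scale
  set.seed(54)
  a <- rnorm(60); b <- rnorm(80) + 1
  r <- mann_whitney(a, b)
  expect_equal(r$method, "normal_approx")
  expect_lt(r$p_value, 0.001)
})

test_that("chi_square_2x2 matches the expected-counts oracle and guards marginals", {
  r <- chi_square_2x2(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0098, tolerance = 1e-2)
  r <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 1, 1), 2, byrow = TRUE)),
               "marginal")
})

test_that("logistic_or reproduces the sample odds ratio and flags degeneracy", {
  x <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
  r <- logistic_or(y, list(exposure = x))
  expect_equal(r$or_value, 6.0, tolerance = 1e-6)
  expect_equal(r$model, "univariate")
  expect_true(r$ci_low <= r$or_value && r$or_value <= r$ci_high)
  # independent predictor: OR exactly 1 on a balanced table
  x <- rep(c(1, 1, 0, 0), c(25, 25, 25, 25))
  y <- rep(c(1, 0, 1, 0), c(25, 25, 25, 25))
  r <- logistic_or(y, list(exposure = x))
  expect_equal(r$or_value, 1.0, tolerance = 1e-6)
  expect_error(logistic_or(rep(1, 50), list(x = rbinom(50, 1, 0.5))),
               "degenerate outcome")
  # perfect separation is reported, naming the predictor
  x <- rep(c(1, 0), each = 30)
  expect_error(logistic_or(x, list(sep = x)), "sep")
  # two predictors -> multiple model
  set.seed(55)
  a <- rbinom(200, 1, 0.5); b <- rbinom(200, 1, 0.5)
  yy <- rbinom(200, 1, plogis(-0.5 + 0.5 * a + 0.3 * b))
  r <- logistic_or(yy, list(a = a, b = b))
  expect_equal(r$model, c("multiple", "multiple"))
  expect_equal(nrow(r), 2L)
})

test_that("association suite joins stages and guards tiny corpora", {
  sim <- generate_corpus(simulation_config(n_trials = 300, seed = 60))
  ppr <- ppr_for_corpus(sim$corpus)
  sgr <- score_corpus(sim$corpus)
  prof <- profile_corpus(sim$corpus)
  res <- run_association_suite(sim$corpus, ppr, sgr, prof)
  expect_s3_class(res, "association_results")
  expect_true(all(c("trend_share", "trend_ppr", "mw_ppr_leading",
                    "chisq_sgr_leading", "or_table") %in% names(res)))
  ps <- c(res$trend_share$p_value, res$trend_ppr$p_value,
          res$mw_ppr_leading$p_value, res$chisq_sgr_leading$p_value,
          res$chisq_sgr_optimal$p_value, res$or_table$p_value)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_equal(nrow(res$or_table), 4L) # 2 univariate + 2 multiple rows
  with(res$or_table,
       expect_true(all(ci_low <= or_value & or_value <= ci_high)))
  one <- new_corpus(make_trial())
  expect_error(
    run_association_suite(one, ppr_for_corpus(one), NULL,
                          profile_corpus(one)),
    "at least 3")
  # JSON serialization round-trips numerically
  path <- tempfile(fileext = ".json")
  write_association_results(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$median_ppr$median, res$median_ppr$median)
})
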