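test_that("ordered-quantile normalization hits exact normal quantiles", {
  x <- c(3.2, 10, -1, 0.5, 7)
  got <- sort(normalize_orq(x))
  want <- qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(got, want, tolerance = 1e-12)
  # idempotent on a quantile grid
  expect_equal(sort(normalize_orq(want)), want, tolerance = 1e-12)
  # rank-preserving for arbitrary input
  withr::local_seed(30)
  y <- rexp(50)^2
  expect_identical(rank(normalize_orq(y)), rank(y))
  expect_error(normalize_orq(rep(2, 10)), "identical")
  expect_error(normalize_orq(c(1, 2)), "at least 3")
})

test_that("normalized continuous draws pass a normality test", {
  withr::local_seed(31)
  ok <- sum(replicate(40, {
    z <- normalize_orq(rexp(100)^3)
    stats::shapiro.test(z)$p.value > 0.01
  }))
  expect_gte(ok, 38)
})

test_that("condition contrast recovers a strong known shift with direction", {
  withr::local_seed(32)
  hits <- 0
  for (k in 1:20) {
    tab <- sim_obs_table(20, 30, shift = 0.8)
    ct <- condition_contrast(tab)
    if (ct$p < 0.001 && ct$direction == "B") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("identical values in both conditions give a null contrast", {
  withr::local_seed(33)
  half <- tidyr::expand_grid(
    subject = sprintf("S%02d", 1:8), pair = sprintf("p%02d", 1:5)
  )
  half$value <- rnorm(nrow(half))
  tab <- dplyr::bind_rows(
    dplyr::mutate(half, condition = "A"),
    dplyr::mutate(half, condition = "B")
  )
  ct <- suppressWarnings(condition_contrast(tab))
  expect_lt(ct$f, 1e-6)
  expect_gt(ct$p, 0.99)
  td <- tidy(ct)
  expect_identical(td$term, "condition")
  expect_identical(glance(ct)$nobs, nrow(tab))
})

test_that("single-subject tables fall back to fixed-effects ANOVA", {
  withr::local_seed(34)
  tab <- sim_obs_table(1, 30, shift = 1)
  expect_warning(ct <- condition_contrast(tab), "single subject")
  expect_identical(ct$method, "anova")
  expect_true(is.finite(ct$p))
})

test_that("effect-size conversions follow the 2t/sqrt(df) convention", {
  expect_equal(cohens_d_from_t(3, 100), 0.6, tolerance = 1e-12)
  expect_equal(cohens_d_from_t(0, 50), 0, tolerance = 1e-12)
  expect_equal(cohens_d_from_f(59.36, 264), 2 * sqrt(59.36) / sqrt(264),
               tolerance = 1e-12)
  # the printed headline statistic reproduces the printed effect size
  expect_equal(round(cohens_d_from_f(59.36, 264), 2), 0.95)
  expect_error(cohens_d_from_f(2, 0), "positive")
  expect_error(cohens_d_from_f(-1, 10), "non-negative")
})

test_that("BH correction equals the exhaustive step-up oracle", {
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  r <- fdr_bh(p4, 0.05)
  expect_true(all(r$reject))
  expect_true(all(!fdr_bh(rep(1, 6))$reject))
  expect_true(fdr_bh(0.04, 0.05)$reject)
  expect_identical(nrow(fdr_bh(numeric(0))), 0L)

  withr::local_seed(35)
  for (k in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_identical(fdr_bh(p, 0.05)$reject, bh_reject_bruteforce(p, 0.05))
  }
  # adjusted p-values are monotone in the raw ordering
  p <- runif(20)
  adj <- fdr_bh(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("Bayes factors accumulate evidence with sample size", {
  withr::local_seed(36)
  bf_small <- median(replicate(10, bayes_factor_condition(sim_obs_table(10, 10, 0.5))))
  bf_big <- median(replicate(10, bayes_factor_condition(sim_obs_table(20, 20, 0.5))))
  expect_gt(bf_big, bf_small)
  expect_gt(bf_big, 1)
})

test_that("replication ratio grows when a strong original is exactly duplicated", {
  withr::local_seed(37)
  orig <- sim_obs_table(15, 20, shift = 0.8)
  r <- replication_bf(orig, orig)
  expect_gt(r$ratio, 1)
  expect_identical(r$verdict %in% c("replicated", "decisive"), r$ratio >= 3)
  expect_error(replication_bf(orig, orig[0, ]), "empty")
  td <- tidy(r)
  expect_identical(names(td), c("bf_original", "bf_joint", "ratio", "verdict"))
})

test_that("replication ratio is invariant to which original rows come first", {
  withr::local_seed(38)
  orig <- sim_obs_table(12, 10, shift = 0.8)
  repl <- sim_obs_table(12, 10, shift = 0.8)
  r1 <- replication_bf(orig, repl)
  r2 <- replication_bf(orig[sample(nrow(orig)), ], repl)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-6)
})

test_that("direction tables extract both directions of a region pair", {
  res <- tibble::tibble(
    subject = "S01", task = "VFR", condition = "encoding",
    source_channel = c("a1", "p1"), target_channel = c("p1", "a1"),
    source_region = c("AI", "PCC/Pr"), target_region = c("PCC/Pr", "AI"),
    n_trials = 3L, pte_mean = c(0.6, 0.4), tau_median = 10, bins_median = 8
  )
  tab <- direction_table(res, "AI", "PCC/Pr")
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$condition, c("AI->PCC/Pr", "PCC/Pr->AI"))
  expect_identical(unique(tab$pair), "a1|p1")
  expect_error(direction_table(res, "AI", "MFG"), "no pairs")
})
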