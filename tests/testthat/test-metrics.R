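# Metric identities, Cohen's kappa, and Shapiro-gated paired comparisons.

test_that("confusion counts and metrics match their defining formulas", {
  ms <- compute_metrics(c(rep(1, 10), rep(0, 90)),
                        c(rep(1, 8), 0, 0, rep(0, 88), 1, 1))
  expect_identical(c(ms$tp, ms$fp, ms$tn, ms$fn), c(8L, 2L, 88L, 2L))
  expect_equal(ms$accuracy, 0.96)
  expect_equal(ms$precision, 0.8)
  expect_equal(ms$recall, 0.8)
  expect_equal(ms$f1, 0.8)
  perfect <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))
})

test_that("metric identities hold over random confusion tables (property sweep)", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    truth <- stats::rbinom(n, 1, stats::runif(1, 0.1, 0.9))
    pred <- stats::rbinom(n, 1, stats::runif(1, 0.1, 0.9))
    ms <- compute_metrics(pred, truth)
    expect_identical(ms$tp + ms$fp + ms$tn + ms$fn, n)
    expect_equal(ms$accuracy, (ms$tp + ms$tn) / n)
    if (ms$precision_defined) expect_equal(ms$precision, ms$tp / (ms$tp + ms$fp))
    if (ms$recall_defined) expect_equal(ms$recall, ms$tp / (ms$tp + ms$fn))
    if (ms$precision_defined && ms$recall_defined &&
        (ms$precision + ms$recall) > 0)
      expect_equal(ms$f1, 2 * ms$precision * ms$recall /
                     (ms$precision + ms$recall))
    expect_true(all(unlist(ms[c("accuracy", "f1")]) >= 0 &
                    unlist(ms[c("accuracy", "f1")]) <= 1))
  }
})

test_that("degenerate predictions flag undefined precision and zero f1", {
  ms <- compute_metrics(rep(0, 10), c(rep(0, 8), 1, 1))
  expect_false(ms$precision_defined)
  expect_true(is.na(ms$precision))
  expect_equal(ms$recall, 0)
  expect_equal(ms$f1, 0)
  expect_error(compute_metrics(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(compute_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("Cohen's kappa matches the hand-computed contingency oracle", {
  a <- c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1)
  b <- c(1, 0, 0, 0, 1, 0, 0, 1, 1, 1)
  # by hand: p_o = 8/10; marginals 0.5 each -> p_e = 0.5; kappa = 0.6
  expect_equal(cohen_kappa(a, b), 0.6)
  expect_equal(cohen_kappa(b, a), 0.6)  # rater symmetry
  expect_equal(cohen_kappa(a, a), 1)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1)  # p_e = 1, perfect
  expect_error(cohen_kappa(rep(1, 5), rep(0, 5) + rep(1, 5) * 0), NA) # runs
})

test_that("kappa of independent raters is ~0 and never exceeds 1", {
  set.seed(10)
  a <- stats::rbinom(10000, 1, 0.3)
  b <- stats::rbinom(10000, 1, 0.6)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  for (i in 1:20) {
    x <- stats::rbinom(50, 1, 0.5); y <- stats::rbinom(50, 1, 0.5)
    expect_lte(cohen_kappa(x, y), 1)
  }
})

test_that("the Shapiro gate selects the paired t-test or Wilcoxon correctly", {
  set.seed(21)
  a <- stats::rnorm(12, 0.8, 0.02)
  b <- a + 0.05 + stats::rnorm(12, 0, 0.01)   # normal differences
  cr <- compare_paired(a, b)
  expect_identical(cr$test, "paired-t")
  expect_gt(cr$shapiro_p, cr$alpha)
  expect_lt(cr$p_value, 0.01)
  expect_gt(cr$mean_difference, 0)
  # heavy-tailed differences force the Wilcoxon branch
  set.seed(22)
  d <- stats::rcauchy(15) * 0.05
  d <- d + 0.2
  b2 <- a2 <- stats::rnorm(15, 0.5, 0.01)
  b2 <- a2 + d
  cr2 <- compare_paired(a2, b2)
  expect_lt(cr2$shapiro_p, 0.05)
  expect_identical(cr2$test, "wilcoxon")
})

test_that("identical series report no difference without running a test", {
  a <- c(0.91, 0.93, 0.90, 0.94)
  cr <- compare_paired(a, a)
  expect_identical(cr$test, "none")
  expect_true(is.na(cr$p_value))
  expect_error(compare_paired(1:2, 2:3), "at least 3")
})

test_that("a 0.1 shift with small noise is detected in >= 95% of replicates", {
  # power simulation at k = 10 folds, 500 seeded replicates
  hits <- withr::with_seed(777, {
    sum(vapply(1:500, function(i) {
      a <- stats::rnorm(10, 0.8, 0.05)
      b <- a + 0.1 + stats::rnorm(10, 0, 0.05)
      compare_paired(a, b)$p_value < 0.05
    }, logical(1)))
  })
  expect_gte(hits / 500, 0.95)
})
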