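test_that("tau-b is +/-1 for perfectly concordant/discordant data", {
  r <- c(1, 2, 3, 4)
  expect_equal(kendall_tau_b(r, c(0.1, 0.2, 0.3, 0.4))$tau_b, 1)
  expect_equal(kendall_tau_b(r, c(0.4, 0.3, 0.2, 0.1))$tau_b, -1)
})

test_that("tau-b matches exhaustive pair enumeration, with and without ties", {
  expect_equal(kendall_tau_b(c(1, 1, 2, 3), c(0.2, 0.1, 0.3, 0.25))$tau_b,
               oracle_tau_b(c(1, 1, 2, 3), c(0.2, 0.1, 0.3, 0.25)))
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(c(20, 80, 200), 1)
    x <- sample(1:4, n, replace = TRUE)                     # heavy rating ties
    y <- round(runif(n), 2)                                 # occasional score ties
    got <- kendall_tau_b(x, y)
    expect_equal(got$tau_b, oracle_tau_b(x, y), tolerance = 1e-12)
    # significance agrees with the tie-corrected normal approximation in cor.test
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(got$tau_b, unname(ct$estimate), tolerance = 1e-12)
    if (n > 20) expect_equal(got$p_value, ct$p.value, tolerance = 1e-8)
  }
  expect_error(kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "tied")
})

test_that("ordinal ratings map onto the package level ordering", {
  got <- kendall_tau_b(c("minimal", "mild", "moderate", "marked"),
                       c(0.1, 0.2, 0.3, 0.4))
  expect_equal(got$tau_b, 1)
})

test_that("dichotomize implements both classification tasks", {
  r <- c("minimal", "mild", "moderate", "marked")
  lh <- dichotomize(r, "low_vs_high")
  expect_equal(lh$labels, c(0L, 0L, 1L, 1L))
  expect_equal(lh$n_pos + lh$n_neg, 4L)
  mm <- dichotomize(r, "minimal_vs_marked")
  expect_equal(mm$labels, c(0L, 1L))
  expect_equal(sum(mm$keep), 2L)
  # a test-set composition of 99/159/78/14 exams gives 258 low vs 92 high
  ratings <- rep(bpe_levels, times = c(99, 159, 78, 14))
  d <- dichotomize(ratings, "low_vs_high")
  expect_equal(d$n_neg, 258L)
  expect_equal(d$n_pos, 92L)
  expect_error(dichotomize(c("minimal", "mild"), "minimal_vs_marked"), "empty")
})

test_that("empirical AUC matches exhaustive pair counting", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(suppressWarnings(roc_analysis(rep(1, 10), rep(c(0, 1), 5))$auc), 0.5)
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(c(30, 100, 200), 1)
    sc <- round(rnorm(n), 1)                                # ties likely
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(roc_analysis(sc, lb)$auc, oracle_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("the empirical ROC curve integrates to the Mann-Whitney AUC", {
  set.seed(103)
  sc <- c(rnorm(40), rnorm(30, 1)); lb <- rep(c(0, 1), c(40, 30))
  r <- roc_analysis(sc, lb)
  cp <- r$curve_points
  expect_equal(cp$fpr[1], 0); expect_equal(cp$tpr[1], 0)
  expect_equal(cp$fpr[nrow(cp)], 1); expect_equal(cp$tpr[nrow(cp)], 1)
  expect_true(all(diff(cp$fpr) >= 0) && all(diff(cp$tpr) >= 0))
  trap <- sum(diff(cp$fpr) * (head(cp$tpr, -1) + tail(cp$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC and tau-b respect symmetry and monotone-transform invariance", {
  set.seed(105)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  a <- roc_analysis(sc, lb)$auc
  expect_equal(roc_analysis(sc, 1 - lb)$auc, 1 - a, tolerance = 1e-12)
  expect_equal(roc_analysis(exp(2 * sc), lb)$auc, a, tolerance = 1e-12)
  x <- sample(1:4, 60, replace = TRUE)
  expect_equal(kendall_tau_b(x, exp(sc))$tau_b, kendall_tau_b(x, sc)$tau_b,
               tolerance = 1e-12)
})

test_that("DeLong standard errors agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(107)
  for (rep in 1:3) {
    sc <- c(rnorm(50), rnorm(40, 0.8)); lb <- rep(c(0, 1), c(50, 40))
    got <- roc_analysis(sc, lb)
    ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(got$se^2, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni correction multiplies and caps the raw p-value", {
  set.seed(109)
  sc <- c(rnorm(30), rnorm(30, 0.5)); lb <- rep(c(0, 1), c(30, 30))
  r1 <- roc_analysis(sc, lb, n_comparisons = 1)
  r13 <- roc_analysis(sc, lb, n_comparisons = 13)
  expect_equal(r13$p_corrected, min(1, r1$p_vs_chance * 13))
  r_big <- roc_analysis(sc, lb, n_comparisons = 1e9)
  expect_equal(r_big$p_corrected, 1)
})

test_that("the binormal option recovers the AUC of binormal data", {
  set.seed(111)
  sc <- c(rnorm(300), rnorm(300, 1.2, 1)); lb <- rep(c(0, 1), c(300, 300))
  r <- roc_analysis(sc, lb, method = "binormal")
  true_auc <- pnorm(1.2 / sqrt(2))
  expect_lt(abs(r$binormal$auc - true_auc), 0.06)
  expect_lt(abs(r$binormal$auc - r$auc), 0.06)
})

test_that("ratio tables pair before/after scores and aggregate by size", {
  rec <- data.frame(
    exam_id = rep(c("a", "b"), each = 2), region = "affected",
    projection_type = "MIP", time_point = 2L, rescale_mode = "original",
    lesion_removed = rep(c(FALSE, TRUE), 2),
    score = c(10, 9, 20, 20), rating = rep(c("minimal", "marked"), each = 2),
    stringsAsFactors = FALSE)
  sizes <- data.frame(exam_id = c("a", "b"), lesion_size_mm = c(25, 5))
  tab <- ratio_vs_size_table(rec, sizes)
  expect_equal(tab$per_exam$ratio, c(0.9, 1))
  expect_equal(nrow(tab$by_level), 2L)
  expect_true(all(tab$per_exam$ratio[tab$per_exam$lesion_size_mm > 10] <= 1))
})
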