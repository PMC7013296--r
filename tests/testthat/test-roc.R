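test_that("AUC handles separation, ties, and the pair-counting oracle", {
  suppressWarnings(
    expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  )
  suppressWarnings(
    expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  )
  expect_equal(roc_auc(c(0.2, 0.9, 0.4, 0.8), c(0, 1, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the tie-adjusted Mann-Whitney statistic", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    auc <- suppressWarnings(roc_auc(scores, labels)$auc)
    expect_equal(auc, pair_count_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("DeLong variance and CI agree with pROC on fixed data", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- c(rnorm(40, 1), rnorm(50))
  labels <- rep(c(1, 0), c(40, 50))
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$var_auc, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-12)
  # CI bounds agree to within the logit-vs-Wald transform difference
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_lt(abs(ours$ci_low - ci[1]), 0.02)
  expect_lt(abs(ours$ci_high - ci[3]), 0.02)
})

test_that("threshold table uses the inclusive >= convention", {
  roc <- suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  th <- roc$thresholds
  expect_equal(th$sensitivity[th$cutoff == 3], 1)
  expect_equal(th$specificity[th$cutoff == 3], 1)
  expect_equal(th$sensitivity[th$cutoff == 1], 1)
  expect_equal(th$specificity[th$cutoff == 1], 0)
})

test_that("degenerate AUC returns a point interval with a warning", {
  expect_warning(r <- roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), "degenerate")
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
})

test_that("comparing a classifier with itself gives z = 0, p = 1", {
  set.seed(4)
  s <- rnorm(30)
  y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.5, 0.5))
  res <- delong_compare(s, s, y)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  # internal consistency: single-AUC variance equals roc_auc's
  expect_equal(res$var_a, roc_auc(s, y)$var_auc, tolerance = 1e-15)
})

test_that("correlated-AUC comparison matches pROC and a bootstrap oracle", {
  skip_if_not_installed("pROC")
  set.seed(31)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  sa <- y + rnorm(n)
  sb <- 0.5 * y + rnorm(n)
  ours <- delong_compare(sa, sb, y)
  ra <- pROC::roc(y, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-10)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-10)

  # variance of the AUC difference vs case-resampling bootstrap
  set.seed(8)
  boot <- replicate(2000, {
    ix_p <- sample(which(y == 1), replace = TRUE)
    ix_n <- sample(which(y == 0), replace = TRUE)
    ix <- c(ix_p, ix_n)
    suppressWarnings(
      roc_auc(sa[ix], y[ix])$auc - roc_auc(sb[ix], y[ix])$auc
    )
  })
  expect_lt(abs(var(boot) - ours$var_diff) / ours$var_diff, 0.3)
})

test_that("Youden cut-off equals an exhaustive scan; metrics match 2x2", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.55, 0.6, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  roc <- roc_auc(scores, labels)
  cm <- youden_cutoff(roc)
  # oracle: scan every observed threshold
  js <- vapply(scores, function(cc) {
    sens <- mean(scores[labels == 1] >= cc)
    spec <- mean(scores[labels == 0] < cc)
    sens + spec - 1
  }, 1)
  best <- min(scores[js >= max(js) - 1e-12])
  expect_equal(cm$cutoff, best)
  expect_equal(cm$youden, max(js))
  # 2x2 consistency
  pred <- scores >= cm$cutoff
  expect_equal(cm$ppv, sum(pred & labels == 1) / sum(pred))
  expect_equal(cm$npv, sum(!pred & labels == 0) / sum(!pred))

  # perfect separation: sens = spec = 1
  r2 <- suppressWarnings(roc_auc(c(1, 2, 8, 9), c(0, 0, 1, 1)))
  cm2 <- youden_cutoff(r2)
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 1)

  # all ties: Youden index 0 everywhere, lowest cutoff returned
  r3 <- suppressWarnings(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)))
  cm3 <- youden_cutoff(r3)
  expect_equal(cm3$youden, 0)
  expect_equal(cm3$cutoff, 2)
})

test_that("DeLong CI shrinks with sample size on nested samples", {
  set.seed(17)
  big_pos <- rnorm(400, 1)
  big_neg <- rnorm(400)
  widths <- vapply(c(40, 100, 400), function(n) {
    r <- roc_auc(c(big_pos[1:n], big_neg[1:n]), rep(c(1, 0), each = n))
    r$ci_high - r$ci_low
  }, 1)
  expect_true(all(diff(widths) < 0))
})
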