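test_that("confusion table counts exactly and rejects malformed input", {
  t1 <- confusion_table(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(t1)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  t2 <- confusion_table(rep(0, 3), rep(1, 3))
  expect_equal(t2$fn, 3L); expect_equal(t2$tp + t2$fp + t2$tn, 0L)
  expect_error(confusion_table(c(1, 0), c(1)), "lengths differ")
  expect_error(confusion_table(c(1, 2), c(1, 0)), "binary")
  # permutation invariance
  set.seed(1); p <- rbinom(30, 1, 0.5); t <- rbinom(30, 1, 0.5)
  i <- sample(30)
  expect_equal(unclass(confusion_table(p[i], t[i])), unclass(confusion_table(p, t)))
})

test_that("the study's image-level table yields its printed operating point", {
  # 88 analysed images: 5 infected (all called positive), 14 false positives,
  # 69 true negatives
  tab <- confusion_from_counts(tp = 5, fn = 0, fp = 14, tn = 69)
  m <- sensitivity_specificity(tab)
  expect_equal(m$sensitivity$estimate, 1)
  expect_equal(round(100 * m$specificity$estimate, 2), 83.13)
  expect_true(m$sensitivity$lower <= 1 && m$sensitivity$upper >= 1)
  expect_true(m$specificity$lower <= m$specificity$estimate &&
              m$specificity$estimate <= m$specificity$upper)
  # same table built from label vectors
  pred <- c(rep(1, 5), rep(1, 14), rep(0, 69))
  truth <- c(rep(1, 5), rep(0, 83))
  expect_equal(unclass(confusion_table(pred, truth)), unclass(tab))
  expect_error(sensitivity_specificity(confusion_from_counts(0, 0, 1, 1)),
               "undefined metric")
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  tab <- confusion_from_counts(tp = 5, fn = 0, fp = 14, tn = 69)
  m <- sensitivity_specificity(tab)
  expect_equal(m$sensitivity$lower, binom.test(5, 5)$conf.int[1])
  expect_equal(m$specificity$upper, binom.test(69, 83)$conf.int[2])
})

test_that("kappa is 1 on identical raters, 0 on the independence example, symmetric", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  set.seed(12)
  a <- rbinom(40, 1, 0.4); b <- rbinom(40, 1, 0.6)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)), "degenerate marginals")
  expect_error(cohens_kappa(1, 1), "at least 2")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (rep in 1:20) {
    a <- rbinom(50, 1, runif(1, 0.2, 0.8))
    b <- ifelse(runif(50) < 0.7, a, 1 - a)
    if (length(unique(a)) < 2 && length(unique(b)) < 2) next
    tab <- table(factor(a, 0:1), factor(b, 0:1))
    expect_equal(cohens_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separation, reversal, and matches brute-force Youden search", {
  roc <- roc_and_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(roc$auc, 1)
  expect_equal(roc$optimal_threshold, 0.5)   # midpoint convention
  anti <- roc_and_cutoff(c(0.8, 0.9, 0.1, 0.2), c(0, 0, 1, 1))
  expect_equal(anti$auc, 0)
  expect_error(roc_and_cutoff(c(0.1, 0.9), c(1, 1)), "single-class")

  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    roc <- roc_and_cutoff(scores, truth)
    expect_equal(max(roc$points$youden), brute_best_youden(scores, truth),
                 tolerance = 1e-12)
    # the reported optimum attains the maximal J
    t <- roc$optimal_threshold
    tpr <- sum(scores >= t & truth == 1) / sum(truth == 1)
    fpr <- sum(scores >= t & truth == 0) / sum(truth == 0)
    expect_equal(tpr - fpr, max(roc$points$youden), tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (rep in 1:10) {
    n <- 30
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- runif(n) + 0.3 * truth
    roc <- roc_and_cutoff(scores, truth)
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    u <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
    expect_equal(roc$auc, u, tolerance = 1e-12)
    expect_equal(roc$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("Youden ties break toward the lower threshold (higher sensitivity)", {
  # two thresholds attain the same J; the lower one must be reported
  scores <- c(0.1, 0.4, 0.6, 0.9)
  truth <- c(0, 1, 0, 1)
  roc <- roc_and_cutoff(scores, truth)
  best <- roc$points$threshold[roc$points$youden == max(roc$points$youden)]
  expect_equal(roc$optimal_threshold, min(best))
})
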