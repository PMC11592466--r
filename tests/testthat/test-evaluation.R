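test_that("confusion counts and their symmetry under prediction flips", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unclass(cm)[c("ta", "tb", "fa", "fb")],
               list(ta = 2L, tb = 1L, fa = 0L, fb = 0L))
  y <- c(1, 1, 0, 0, 1, 0)
  p <- c(1, 0, 0, 1, 1, 0)
  a <- confusion(y, p)
  b <- confusion(y, 1 - p)
  expect_equal(b$ta, a$fb); expect_equal(b$fb, a$ta)
  expect_equal(b$tb, a$fa); expect_equal(b$fa, a$tb)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics agree with a naive per-sample counting oracle", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(5:60, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      p <- rbinom(n, 1, 0.5)
      m <- compute_metrics(confusion(y, p))
      expect_equal(m$accuracy, 100 * mean(y == p))
      if (sum(p) > 0) {
        expect_equal(m$precision, 100 * sum(y == 1 & p == 1) / sum(p == 1))
      }
      expect_equal(m$sensitivity, 100 * sum(y == 1 & p == 1) / sum(y == 1))
      expect_equal(m$specificity, 100 * sum(y == 0 & p == 0) / sum(y == 0))
    }
  })
})

test_that("metric values reproduce the recovered benchmark rows", {
  # weighted-averaging ensemble row: counts recovered by enumeration
  m <- compute_metrics(confusion_matrix(ta = 35, tb = 11, fa = 4, fb = 2))
  expect_equal(round_half_up(unlist(m), 2),
               c(accuracy = 88.46, precision = 89.74, sensitivity = 94.59,
                 specificity = 73.33, f_value = 92.11, mcc = 71.07))
  # strongest base learner (gradient boosting) row
  m2 <- compute_metrics(confusion_matrix(ta = 33, tb = 11, fa = 5, fb = 3))
  expect_equal(round_half_up(unlist(m2), 2),
               c(accuracy = 84.62, precision = 86.84, sensitivity = 91.67,
                 specificity = 68.75, f_value = 89.19, mcc = 62.87))
  # perfect classifier
  m3 <- compute_metrics(confusion_matrix(10, 10, 0, 0))
  expect_true(all(unlist(m3) == 100))
  # degenerate denominators reported as NA, not errors
  m4 <- compute_metrics(confusion_matrix(0, 5, 0, 5))
  expect_true(is.na(m4$precision))
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("the literal F-value form differs from the standard one", {
  cm <- confusion_matrix(ta = 35, tb = 11, fa = 4, fb = 2)
  expect_equal(compute_metrics(cm, f_value = "literal")$f_value,
               100 * 70 / 74)
  expect_gt(abs(compute_metrics(cm, f_value = "literal")$f_value -
                  compute_metrics(cm)$f_value), 0.5)
})

test_that("AUC equals the pairwise rank statistic with tie handling", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(22, {
    for (i in 1:20) {
      n <- sample(6:40, 1)
      y <- c(0, 1, rbinom(n, 1, 0.4))
      s <- round(runif(n + 2), 1)  # coarse scores force ties
      expect_equal(roc_auc(s, y)$auc, auc_brute(s, y))
      # invariance under strictly increasing transform
      expect_equal(roc_auc(exp(3 * s), y)$auc, roc_auc(s, y)$auc)
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    y <- c(0, 1, rbinom(40, 1, 0.5))
    s <- runif(42)
    expect_equal(roc_auc(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  })
})

test_that("ROC points trace the empirical step curve", {
  ra <- roc_auc(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
})

test_that("integer confusion matrices are recovered uniquely from rates", {
  s1 <- infer_confusion_matrix(88.46, 89.74, 94.59, 73.33)
  expect_true(attr(s1, "unique"))
  expect_equal(unlist(s1[1, c("ta", "fa", "fb", "tb")]),
               c(ta = 35, fa = 4, fb = 2, tb = 11))
  s2 <- infer_confusion_matrix(84.62, 86.84, 91.67, 68.75)
  expect_true(attr(s2, "unique"))
  expect_equal(unlist(s2[1, c("ta", "fa", "fb", "tb")]),
               c(ta = 33, fa = 5, fb = 3, tb = 11))
  # impossible combination: perfect rates with zero specificity
  s3 <- infer_confusion_matrix(100, 100, 100, 0)
  expect_equal(nrow(s3), 0)
})

test_that("every published row is self-consistent at 2 decimals", {
  audit <- audit_published_metrics()
  expect_equal(nrow(audit), 9)
  expect_true(all(audit$n_solutions == 1))
  expect_true(all(audit$consistent))
  # the recovered matrices all imply 52 held-out samples
  expect_true(all(audit$total == 52))
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(2.344999, 2), 2.34)
  expect_equal(round_half_up(71.065, 2), 71.07)
})
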