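test_that("confusion counts partition the sample and match a loop oracle", {
  expect_equal(confusionAtThreshold(c(0.9, 0.1), c(1, 0), 0.5),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(sum(confusionAtThreshold(c(0.9, 0.1), c(1, 0), 0)[c("TP", "FP")]),
               2L)  # t = 0: everyone predicted positive
  expect_error(confusionAtThreshold(numeric(0), numeric(0), 0.5), "empty")

  set.seed(21)
  s <- runif(1000); y <- rbinom(1000, 1, 0.3)
  cm <- confusionAtThreshold(s, y, 0.4)
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:1000) {
    if (s[i] >= 0.4) { if (y[i] == 1) tp <- tp + 1L else fp <- fp + 1L }
    else { if (y[i] == 1) fn <- fn + 1L else tn <- tn + 1L }
  }
  expect_equal(cm, c(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_equal(sum(cm), 1000L)
})

test_that("ratio metrics are exact and undefined on zero denominators", {
  expect_equal(ppv(10, 30), 0.25)
  expect_equal(sensitivity(10, 30), 0.25)
  expect_true(is.na(ppv(0, 0)))
  expect_true(is.na(f1Score(NA_real_, 0.5)))
  expect_equal(f1Score(0.5, 0.5), 0.5)
  # F1 from rates equals F1 from counts
  cm <- c(TP = 37, FP = 13, TN = 80, FN = 21)
  f_rates <- f1Score(ppv(cm[["TP"]], cm[["FP"]]),
                     sensitivity(cm[["TP"]], cm[["FN"]]))
  f_counts <- 2 * cm[["TP"]] / (2 * cm[["TP"]] + cm[["FP"]] + cm[["FN"]])
  expect_equal(f_rates, f_counts, tolerance = 1e-12)
})

test_that("AUROC equals O(n^2) pair counting with ties at 1/2", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aurocScore(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(aurocScore(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(22)
  s <- round(runif(200), 2)  # rounding forces ties
  y <- rbinom(200, 1, 0.4)
  pos <- s[y == 1]; neg <- s[y == 0]
  brute <- 0
  for (a in pos) for (b in neg)
    brute <- brute + (a > b) + 0.5 * (a == b)
  brute <- brute / (length(pos) * length(neg))
  expect_equal(aurocScore(s, y), brute, tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(aurocScore(qlogis(pmin(pmax(s, 0.01), 0.99)), y),
               aurocScore(pmin(pmax(s, 0.01), 0.99), y), tolerance = 1e-12)
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aurocScore(s, y), ref, tolerance = 1e-12)
})

test_that("bootstrap CI: seeded, degenerate collapse, sane width", {
  set.seed(24)
  s <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  y <- rep(c(1, 0), each = 50)
  ci <- bootstrapCi(s, y, aurocScore, n_boot = 200, seed = 31)
  expect_identical(ci[1:2], bootstrapCi(s, y, aurocScore, n_boot = 200,
                                        seed = 31)[1:2])
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)  # perfect classifier
  s2 <- s + rnorm(100, 0, 0.3)
  ci2 <- bootstrapCi(s2, y, aurocScore, n_boot = 200, seed = 31)
  expect_lte(ci2$lower, ci2$upper)
  expect_lte(ci2$lower, aurocScore(s2, y))
  expect_gte(ci2$upper, aurocScore(s2, y))
})

test_that("DeLong test: identity, antisymmetry, agreement with pROC", {
  set.seed(25)
  y <- rbinom(300, 1, 0.5)
  a <- runif(300) + 0.5 * y
  d0 <- delongTest(a, a, y)
  expect_equal(d0$difference, 0)
  expect_equal(d0$p_value, 1)
  b <- runif(300) + 0.2 * y
  d1 <- delongTest(a, b, y)
  d2 <- delongTest(b, a, y)
  expect_equal(d1$difference, -d2$difference)
  expect_equal(d1$p_value, d2$p_value)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(d1$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("threshold sweep recomposes confusion counts and is monotone", {
  set.seed(26)
  s <- runif(500); y <- rbinom(500, 1, 0.3)
  sw <- thresholdSweep(s, y)
  expect_equal(sw$threshold, seq(0.40, 0.70, by = 0.05))
  expect_true(all(diff(sw$n_predicted_positive) <= 0))
  expect_true(all(sw$n_true_positive <=
                    pmin(sw$n_predicted_positive, sw$n_positives)))
  # conservation: TP + FN = positives at every row
  expect_true(all(sw$n_positives == sum(y)))
  for (i in seq_len(nrow(sw))) {
    cm <- confusionAtThreshold(s, y, sw$threshold[i])
    expect_equal(sw$n_true_positive[i], cm[["TP"]])
    expect_equal(sw$ppv[i], ppv(cm[["TP"]], cm[["FP"]]))
  }
  # threshold 0: PPV equals prevalence
  sw0 <- thresholdSweep(s, y, thresholds = 0)
  expect_equal(sw0$ppv, mean(y))
})

test_that("subgroup report partitions counts and matches subset AUROC", {
  set.seed(27)
  n <- 300
  s <- runif(n); y <- rbinom(n, 1, 0.4)
  g <- sample(c("F", "M"), n, replace = TRUE)
  rep <- subgroupReport(s, y, g, threshold = 0.4)
  pooled <- confusionAtThreshold(s, y, 0.4)
  expect_equal(sum(rep$TP), pooled[["TP"]])
  expect_equal(sum(rep$n), n)
  for (grp in rep$group) {
    i <- g == grp
    expect_equal(rep$auroc[rep$group == grp], aurocScore(s[i], y[i]))
  }
  # identical score/label multisets give identical metrics
  rep2 <- subgroupReport(c(s, s), c(y, y),
                         rep(c("a", "b"), each = n), threshold = 0.4)
  expect_equal(rep2$ppv[1], rep2$ppv[2])
  expect_equal(rep2$auroc[1], rep2$auroc[2])
})

test_that("metrics report fields are coherent", {
  set.seed(28)
  s <- runif(200); y <- rbinom(200, 1, 0.5)
  r <- metricsReport(s, y, threshold = 0.4, n_boot = 50, seed = 1)
  expect_equal(r$positive$precision,
               ppv(r$confusion[["TP"]], r$confusion[["FP"]]))
  expect_equal(r$specificity, r$negative$recall)
  expect_lte(r$auroc_ci$lower, r$auroc)
  expect_gte(r$auroc_ci$upper, r$auroc)
})
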