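# Random-forest stage, confusion metrics, ROC/AUC and the CV harness.

test_that("confusion metrics follow the defining formulas", {
  m <- confusion_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unlist(m[c("Sn", "Sp", "Acc", "MCC")]),
               c(Sn = 1, Sp = 1, Acc = 1, MCC = 1))

  m <- confusion_metrics(c(TP = 8, FP = 1, TN = 9, FN = 2))
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.9)
  expect_equal(m$Acc, 0.85)
  expect_equal(m$MCC, 70 / sqrt(10 * 9 * 10 * 11))
  expect_equal(m$MCC, 0.7035, tolerance = 1e-4)

  # all predicted positive on a balanced set: Sp = 0, Sn = 1, MCC flagged 0
  m <- confusion_metrics(c(TP = 10, FP = 10, TN = 0, FN = 0))
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 0)
  expect_equal(m$MCC, 0)
  expect_true("MCC" %in% m$zero_denominator)
})

test_that("Acc decomposes into class-weighted Sn and Sp, and MCC is
          symmetric under class swap", {
  set.seed(101)
  for (rep_i in 1:30) {
    cnt <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
             TN = sample(0:30, 1), FN = sample(0:30, 1))
    if (sum(cnt) == 0) next
    m <- confusion_metrics(cnt)
    P <- cnt[["TP"]] + cnt[["FN"]]; N <- cnt[["TN"]] + cnt[["FP"]]
    if (P > 0 && N > 0)
      expect_equal(m$Acc, (m$Sn * P + m$Sp * N) / (P + N))
    swapped <- confusion_metrics(c(TP = cnt[["TN"]], FP = cnt[["FN"]],
                                   TN = cnt[["TP"]], FN = cnt[["FP"]]))
    expect_equal(m$MCC, swapped$MCC)
  }
})

test_that("ROC sweep yields AUC equal to the concordance oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c("cis", "cis", "trans", "trans"))
  expect_equal(r$auc, 1)

  set.seed(102)
  for (rep_i in 1:30) {
    n <- sample(8:25, 1)
    y <- c("cis", "trans", sample(c("cis", "trans"), n - 2, TRUE))
    s <- round(stats::runif(n), sample(1:3, 1))   # induce ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc(s, y == "cis"), tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
  expect_error(roc_auc(c(0.1, 0.9), c("cis", "cis")), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(103)
  s <- stats::runif(60)
  y <- sample(c("cis", "trans"), 60, TRUE, prob = c(0.4, 0.6))
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("trans", "cis"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random AUC sits in the null band at n = 1000", {
  set.seed(104)
  s <- stats::runif(1000)
  y <- sample(c("cis", "trans"), 1000, TRUE)
  a <- roc_auc(s, y)$auc
  expect_gt(a, 0.45)
  expect_lt(a, 0.55)
})

test_that("a forest separates a separable toy set and is seed-reproducible", {
  set.seed(105)
  tbl <- toy_table(20, 2, shift = 3)
  model <- train_forest(tbl, forest_spec(seed = 9))
  pred <- predict(model, tbl, type = "label")
  expect_equal(mean(pred == tbl$labels), 1)

  s1 <- predict(train_forest(tbl, forest_spec(seed = 9)), tbl)
  s2 <- predict(train_forest(tbl, forest_spec(seed = 9)), tbl)
  expect_identical(s1, s2)

  one_class <- feature_table(tbl$x, rep("cis", nrow(tbl$x)))
  expect_error(train_forest(one_class), "single class")
})

test_that("forest defaults and the WEKA preset resolve mtry as documented", {
  expect_equal(golgiCSP:::resolve_mtry(forest_spec(), 460), 21)
  expect_equal(golgiCSP:::resolve_mtry(forest_spec(), 4), 2)
  wk <- weka_forest_spec()
  expect_equal(wk$n_trees, 10L)
  expect_equal(golgiCSP:::resolve_mtry(wk, 460), floor(log2(460)) + 1)
})

test_that("pure-noise features give chance-level cross-validation", {
  accs <- vapply(1:20, function(sd) {
    set.seed(1000 + sd)
    tbl <- toy_table(20, 5, shift = 0)
    cross_validate(tbl, folds = 10, seed = sd)$Acc
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("jackknife predicts every sample exactly once and pools counts", {
  set.seed(106)
  tbl <- toy_table(12, 3, shift = 1.5)
  rep_ <- cross_validate(tbl, folds = nrow(tbl$x), seed = 2)
  expect_equal(nrow(rep_$predictions), 24)
  expect_equal(sum(rep_$counts), 24)
  expect_identical(sort(unique(rep_$folds)), 1:24)
})

test_that("strongly separated classes are recovered near-perfectly", {
  set.seed(107)
  tbl <- toy_table(100, 4, shift = 2)
  rep_ <- cross_validate(tbl, folds = 10, seed = 3)
  expect_gte(rep_$Acc, 0.95)
  expect_gte(rep_$auc, 0.98)
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(108)
  tbl <- toy_table(15, 4, shift = 0.5)
  r1 <- cross_validate(tbl, folds = 5, seed = 11, smote = FALSE)
  r2 <- cross_validate(tbl, folds = 5, seed = 11, smote = FALSE)
  expect_identical(r1$predictions$score, r2$predictions$score)
  expect_identical(r1$counts, r2$counts)
})

test_that("independent-set evaluation trains once and scores the test set", {
  set.seed(109)
  train <- toy_table(25, 3, shift = 2)
  test <- toy_table(15, 3, shift = 2)
  rep_ <- evaluate_independent(train, test, smote = FALSE, seed = 4)
  expect_equal(sum(rep_$counts), 30)
  expect_gte(rep_$Acc, 0.9)
})
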