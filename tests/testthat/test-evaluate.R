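# The published per-model confusion matrices (rows: actual MI/HC, columns:
# predicted MI/HC) and the percentage metrics they must reproduce.
published_cms <- list(
  KNN = c(tp = 325, fn = 22, fp = 21, tn = 59),
  SVM = c(tp = 330, fn = 17, fp = 21, tn = 59),
  DT  = c(tp = 323, fn = 24, fp = 17, tn = 63),
  DA  = c(tp = 330, fn = 17, fp = 24, tn = 56),
  ANN = c(tp = 324, fn = 23, fp = 20, tn = 60))

test_that("confusion counts reconstruct the published KNN matrix", {
  cm0 <- published_cms$KNN
  y_true <- c(rep("MI", 347), rep("HC", 80))
  y_pred <- c(rep("MI", cm0["tp"]), rep("HC", cm0["fn"]),
              rep("MI", cm0["fp"]), rep("HC", cm0["tn"]))
  cm <- confusion(y_true, y_pred)
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")], as.list(cm0),
               ignore_attr = TRUE)
  # swapping predictions swaps tp<->fn and tn<->fp
  swapped <- ifelse(y_pred == "MI", "HC", "MI")
  cm2 <- confusion(y_true, swapped)
  expect_equal(cm2$tp, cm$fn); expect_equal(cm2$fn, cm$tp)
  expect_equal(cm2$fp, cm$tn); expect_equal(cm2$tn, cm$fp)
  # all-correct case
  cm3 <- confusion(c(rep("MI", 5), rep("HC", 5)), c(rep("MI", 5), rep("HC", 5)))
  expect_equal(unclass(cm3), list(tp = 5, fn = 0, fp = 0, tn = 5))
})

test_that("the metric suite reproduces the published table at 2 decimals", {
  pct <- function(v) sprintf("%.2f", 100 * v)
  m_knn <- metrics(do.call(confusion_counts, as.list(published_cms$KNN)))
  expect_identical(pct(m_knn$sens), "93.66")
  expect_identical(pct(m_knn$spec), "73.75")
  expect_identical(pct(m_knn$acc), "89.93")
  expect_identical(pct(m_knn$ppv), "93.93")
  expect_identical(pct(m_knn$npv), "72.84")
  m_dt <- metrics(do.call(confusion_counts, as.list(published_cms$DT)))
  expect_identical(pct(m_dt$ppv), "95.00")
  expect_identical(pct(m_dt$acc), "90.40")
  m_svm <- metrics(do.call(confusion_counts, as.list(published_cms$SVM)))
  expect_identical(pct(m_svm$acc), "91.10")
  expect_identical(pct(m_svm$npv), "77.63")
  m_perfect <- metrics(confusion_counts(7, 0, 0, 3))
  expect_true(all(unlist(m_perfect) == 1))
})

test_that("undefined metrics are reported as NA, never zero", {
  m <- metrics(confusion_counts(0, 0, 2, 3))   # no actual MI
  expect_true(is.na(m$sens))
  expect_false(is.na(m$spec))
})

test_that("accuracy is the prevalence-weighted blend of sens and spec", {
  set.seed(81)
  for (rep in 1:20) {
    cm <- confusion_counts(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    m <- metrics(cm)
    prev <- (cm$tp + cm$fn) / (cm$tp + cm$fn + cm$fp + cm$tn)
    expect_equal(m$acc, prev * m$sens + (1 - prev) * m$spec, tolerance = 1e-12)
  }
  y <- c(rep("MI", 4), rep("HC", 3))
  expect_equal(metrics(confusion(y, y))$acc, 1)
})

test_that("AUC equals the rank statistic and exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("MI", "MI", "HC", "HC"))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c("MI", "MI", "HC", "HC"))$auc, 0)
  set.seed(82)
  for (rep in 1:10) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    y <- c(rep("MI", n1), rep("HC", n0))
    s <- round(runif(n1 + n0), 2)              # deliberate ties
    auc <- roc_auc(s, y)$auc
    a <- s[y == "MI"]; b <- s[y == "HC"]
    u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
    curve <- roc_auc(s, y)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(83)
  for (rep in 1:5) {
    y <- c(rep("MI", 30), rep("HC", 20))
    s <- round(runif(50), 2) + 0.3 * (y == "MI")
    ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y, c("HC", "MI")),
                                          predictor = s, quiet = TRUE)))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("the cut-point maximizes Youden J with ties toward sensitivity", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("MI", "MI", "HC", "HC"))
  cp <- cut_point(perfect)
  expect_equal(c(cp$fpr, cp$tpr), c(0, 1))
  # uninformative scores: J = 0 everywhere; the highest-tpr vertex wins
  flat <- roc_auc(rep(0.5, 10), rep(c("MI", "HC"), 5))
  cpf <- cut_point(flat)
  expect_equal(cpf$tpr, 1)
  # three-threshold curve against brute force over vertices
  y <- c("MI", "MI", "MI", "HC", "HC")
  s <- c(0.9, 0.7, 0.3, 0.7, 0.2)
  curve <- roc_auc(s, y)
  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  best <- best[which.max(curve$tpr[best])]
  cp3 <- cut_point(curve)
  expect_equal(cp3$tpr, curve$tpr[best])
  expect_equal(cp3$fpr, curve$fpr[best])
  # the alternative closest-to-corner criterion is available
  expect_named(cut_point(curve, "closest"), c("fpr", "tpr", "threshold"))
})

test_that("reports are canonical, lossless and byte-identical across runs", {
  dir <- withr::local_tempdir()
  empty <- write_report(list(), file.path(dir, "empty.json"))
  expect_identical(length(empty$models), 0L)
  mm <- list(KNN = list(metrics = metrics(confusion_counts(30, 3, 2, 15)),
                        auc = 0.93, per_fold_accuracy = c(0.9, 0.95)),
             STACKING = list(metrics = metrics(confusion_counts(32, 1, 1, 16)),
                             auc = 0.99))
  j1 <- file.path(dir, "r1.json"); j2 <- file.path(dir, "r2.json")
  write_report(mm, j1, file.path(dir, "r1.csv"), meta = list(seed = 1))
  write_report(mm, j2, file.path(dir, "r2.csv"), meta = list(seed = 1))
  expect_identical(readLines(j1), readLines(j2))
  back <- jsonlite::read_json(j1)
  expect_equal(back$models$KNN$auc, 0.93)
  expect_equal(back$models$KNN$metrics$sens, 30 / 33)
  csv <- utils::read.csv(file.path(dir, "r1.csv"))
  expect_identical(csv$model, c("KNN", "STACKING"))
})
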