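test_that("the grid enumerates exactly the published configuration counts", {
  grid <- enumerate_grid()
  expect_length(grid, 210)
  fams <- vapply(grid, `[[`, "", "family")
  counts <- table(fams)
  expect_equal(unname(counts[c("SVM", "DA", "KNN", "DT", "ANN", "NB", "RF",
                               "LR", "EM")]),
               c(25, 6, 36, 32, 20, 10, 25, 24, 32), ignore_attr = TRUE)
  # unsupported LR rows are enumerated but flagged
  lr <- grid[fams == "LR"]
  expect_equal(sum(vapply(lr, `[[`, TRUE, "supported")), 8)
  expect_true(all(vapply(grid[fams != "LR"], `[[`, TRUE, "supported")))
  # stable, deterministic order
  ids <- vapply(grid, `[[`, "", "id")
  expect_identical(ids, vapply(enumerate_grid(), `[[`, "", "id"))
  expect_false(anyDuplicated(ids) > 0)
  expect_error(enumerate_grid("XGB"), "unknown family")
})

test_that("fold plans are stratified, deterministic and a true partition", {
  labels <- c(rep("MI", 347), rep("HC", 80))
  plan <- make_folds(labels, k = 10, seed = 5)
  for (f in 1:10) {
    mi <- sum(plan$fold_of == f & labels == "MI")
    hc <- sum(plan$fold_of == f & labels == "HC")
    expect_true(mi %in% c(34, 35))
    expect_equal(hc, 8)
  }
  expect_identical(plan$fold_of, make_folds(labels, k = 10, seed = 5)$fold_of)
  expect_false(identical(plan$fold_of, make_folds(labels, 10, seed = 6)$fold_of))
  expect_identical(sort(unique(plan$fold_of)), 1:10)
  expect_length(plan$fold_of, 427)
  expect_error(make_folds(c(rep("MI", 30), rep("HC", 4)), k = 10), ">= k")
})

make_sep_features <- function(n, seed, sep = TRUE) {
  set.seed(seed)
  labels <- rep(c("MI", "HC"), each = n / 2)
  X <- matrix(rnorm(n * 12, sd = if (sep) 0.01 else 1), n, 12,
              dimnames = list(NULL, feature_names()))
  if (sep) X <- X + as.integer(labels == "MI")   # every feature tracks the label
  list(features = as.data.frame(X), labels = labels)
}

test_that("every family separates a label-valued feature perfectly", {
  d <- make_sep_features(40, seed = 71)
  plan <- make_folds(d$labels, k = 5, seed = 1)
  picks <- c("SVM:poly3/1", "DA:linear", "KNN:5/euclidean/equal",
             "DT:crossentropy/4/5", "ANN:2/10/20", "NB:empirical/kernel/epanechnikov",
             "RF:100/1", "LR:empirical/ridge/bfgs",
             "EM:adaboost/tree/50", "EM:gentleboost/tree/50",
             "EM:rusboost/discriminant/100", "EM:logitboost/tree/50",
             "EM:robustboost/tree/50")
  grid <- enumerate_grid()
  ids <- vapply(grid, `[[`, "", "id")
  for (pk in picks) {
    cf <- grid[[match(pk, ids)]]
    fp <- fit_predict_config(cf, d$features, d$labels, plan, seed = 2)
    expect_equal(mean(fp$per_fold_accuracy), 1, tolerance = 1e-9,
                 label = paste("accuracy of", pk))
  }
})

test_that("shuffled labels give chance-level KNN accuracy", {
  set.seed(72)
  n <- 200
  X <- as.data.frame(matrix(rnorm(n * 12), n, 12,
                            dimnames = list(NULL, feature_names())))
  labels <- sample(rep(c("MI", "HC"), each = n / 2))
  plan <- make_folds(labels, k = 10, seed = 3)
  cf <- enumerate_grid()[[match("KNN:5/euclidean/equal",
                                vapply(enumerate_grid(), `[[`, "", "id"))]]
  fp <- fit_predict_config(cf, X, labels, plan, seed = 4)
  expect_lt(abs(mean(fp$per_fold_accuracy) - 0.5), 0.1)
})

test_that("stochastic families are reproducible for a fixed seed", {
  d <- make_sep_features(30, seed = 73, sep = FALSE)
  plan <- make_folds(d$labels, k = 5, seed = 1)
  grid <- enumerate_grid()
  ids <- vapply(grid, `[[`, "", "id")
  for (pk in c("ANN:2/5/5", "RF:100/1", "EM:rusboost/tree/50")) {
    cf <- grid[[match(pk, ids)]]
    f1 <- fit_predict_config(cf, d$features, d$labels, plan, seed = 9)
    f2 <- fit_predict_config(cf, d$features, d$labels, plan, seed = 9)
    expect_identical(f1$scores, f2$scores, label = pk)
  }
})

test_that("unsupported configurations yield a flagged result, not an error", {
  d <- make_sep_features(30, seed = 74)
  plan <- make_folds(d$labels, k = 5, seed = 1)
  grid <- enumerate_grid("LR")
  unsup <- grid[!vapply(grid, `[[`, TRUE, "supported")][[1]]
  fp <- fit_predict_config(unsup, d$features, d$labels, plan)
  expect_false(fp$supported)
  expect_true(all(is.na(fp$scores)))
})

test_that("the OOF matrix is leakage-free by construction", {
  ft <- study_feature_table()
  d <- list(features = ft, labels = ft$label)
  plan <- make_folds(d$labels, k = 5, seed = 2)
  grid <- enumerate_grid()
  ids <- vapply(grid, `[[`, "", "id")
  preds <- lapply(c("KNN:5/euclidean/inverse", "DA:linear", "NB:uniform/normal"),
                  function(pk) fit_predict_config(grid[[match(pk, ids)]],
                                                  d$features, d$labels, plan))
  oof <- build_oof_matrix(preds)
  expect_equal(dim(oof), c(nrow(ft), 3))
  expect_equal(oof[, 1], preds[[1]]$scores, ignore_attr = TRUE)
  # structural assertion: the scoring model of sample i never trained on i
  tsets <- attr(oof, "train_index_sets")
  for (j in seq_along(tsets))
    for (i in seq_len(nrow(oof)))
      expect_false(i %in% tsets[[j]][[plan$fold_of[i]]])
  # model diversity: no pair of columns is perfectly correlated
  cors <- cor(oof)
  expect_true(all(cors[upper.tri(cors)] < 1 - 1e-9))
})

test_that("stacking exploits a perfect base column and stays at chance on noise", {
  set.seed(76)
  n <- 200
  labels <- rep(c("MI", "HC"), each = n / 2)
  plan <- make_folds(labels, k = 10, seed = 7)
  y01 <- as.integer(labels == "MI")
  oof_perfect <- cbind(perfect = 0.9 * y01 + 0.05,
                       noise1 = runif(n), noise2 = runif(n))
  st <- fit_stacking(oof_perfect, labels, plan)
  expect_equal(mean(st$per_fold_accuracy), 1)
  oof_noise <- matrix(runif(n * 3), n, 3)
  st2 <- fit_stacking(oof_noise, labels, plan)
  expect_lt(abs(mean(st2$per_fold_accuracy) - 0.5), 0.1)
  # single informative base column: the logistic transform is monotone
  # increasing in the score, so the stacked AUC equals the column's AUC
  one <- matrix(0.6 * y01 + 0.4 * runif(n), n, 1)
  st3 <- fit_stacking(one, labels, plan)
  meta_all <- stats::plogis(cbind(1, one) %*% st3$coefficients)
  expect_lt(abs(roc_auc(as.numeric(meta_all), labels)$auc -
                roc_auc(one[, 1], labels)$auc), 1e-9)
})

test_that("permutation importance isolates label-defining features", {
  set.seed(77)
  n <- 100
  labels <- rep(c("MI", "HC"), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * 12), n, 12,
                            dimnames = list(NULL, feature_names())))
  X$areaQRS <- as.integer(labels == "MI") + rnorm(n, sd = 0.05)
  score_fn <- function(f) as.numeric(f$areaQRS > 0.5)
  pif <- permutation_importance(score_fn, X, labels, n_repeats = 30, seed = 5)
  expect_gte(pif[["areaQRS"]], 0.2)
  expect_true(all(abs(pif[setdiff(feature_names(), "areaQRS")]) < 0.05))
  # shuffling constant columns is the identity: importance exactly zero
  Xc <- X; for (fn in feature_names()) Xc[[fn]] <- 1
  pif0 <- permutation_importance(function(f) rep(0.9, nrow(f)), Xc, labels,
                                 n_repeats = 3, seed = 5)
  expect_true(all(pif0 == 0))
})

test_that("stacking dispersion tends below the worst base dispersion", {
  ft <- study_feature_table()
  diffs <- vapply(1:10, function(s) {
    g <- train_grid(ft, ft$label, seed = 1000 + s,
                    families = c("KNN", "DA", "NB", "DT"), k = 10)
    st <- vcg_stack(ft, ft$label, grid = g, seed = 1000 + s, k = 10)
    base_disp <- vapply(g$predictions[best_configs(g)$index],
                        function(p) stats::sd(p$per_fold_accuracy), 0)
    stats::sd(st$per_fold_accuracy) - max(base_disp)
  }, 0)
  expect_lte(mean(diffs), 0)
})
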