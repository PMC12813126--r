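#' Cross-validated out-of-fold predictions for one configuration
#'
#' For each fold of the plan, the model is trained on the other folds (with
#' features centered and scaled using training-fold statistics only) and
#' scores the held-out fold, so every sample is scored exactly once by a
#' model that never saw it. The training index set of every fold is recorded
#' so the no-leakage guarantee can be asserted structurally.
#'
#' @param config A `classifier_config` from [enumerate_grid()].
#' @param features Numeric matrix/data frame (rows = records, the 12 feature
#'   columns).
#' @param labels `"MI"`/`"HC"` labels.
#' @param plan A [make_folds()] plan for these labels.
#' @param seed Seed for stochastic families (fold-wise sub-seeds derived).
#' @return Object of class `fold_predictions`: `scores` (MI score in `[0,1]`
#'   per sample), `labels_pred` (at threshold 0.5), `per_fold_accuracy`,
#'   `train_index_sets`, `fold_of`, `config`, `supported`. Unsupported
#'   configurations yield `supported = FALSE` with `NA` scores (not an
#'   error).
#' @export
fit_predict_config <- function(config, features, labels, plan, seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(as.data.frame(features)[, feature_names(), drop = FALSE])
  y01 <- as.integer(as.character(labels) == "MI")
  n <- nrow(X)
  if (length(plan$fold_of) != n) stopf("fold plan does not match sample count")
  out <- list(config = config, supported = config$supported,
              fold_of = plan$fold_of)
  class(out) <- "fold_predictions"
  if (!config$supported) {
    out$scores <- rep(NA_real_, n)
    out$labels_pred <- rep(NA_character_, n)
    out$per_fold_accuracy <- rep(NA_real_, plan$k)
    out$train_index_sets <- vector("list", plan$k)
    return(out)
  }
  scores <- numeric(n)
  per_fold <- numeric(plan$k)
  train_sets <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- which(plan$fold_of != f)
    te <- which(plan$fold_of == f)
    train_sets[[f]] <- tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg < 1e-12] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    model <- fit_learner(config, Ztr, y01[tr],
                         seed = derive_seed(seed, paste0(config$id, "-f", f)))
    s <- score_learner(model, Zte)
    scores[te] <- s
    per_fold[f] <- mean((s > 0.5) == (y01[te] == 1))
  }
  out$scores <- scores
  out$labels_pred <- ifelse(scores > 0.5, "MI", "HC")
  out$per_fold_accuracy <- per_fold
  out$train_index_sets <- train_sets
  out
}

#' @export
print.fold_predictions <- function(x, ...) {
  if (!x$supported) {
    cat(sprintf("<fold_predictions> %s: unsupported configuration\n", x$config$id))
  } else {
    cat(sprintf("<fold_predictions> %s: OOF accuracy %.4f (fold sd %.4f)\n",
                x$config$id, mean(x$per_fold_accuracy),
                stats::sd(x$per_fold_accuracy)))
  }
  invisible(x)
}

#' Run the classifier grid under cross-validation
#'
#' Evaluates every (supported) configuration with [fit_predict_config()] on
#' one shared fold plan and summarizes the full metric suite per
#' configuration.
#'
#' @param features,labels,seed As in [fit_predict_config()].
#' @param families Optional family subset passed to [enumerate_grid()].
#' @param k Folds (default 10).
#' @param progress Print one line per family as it completes.
#' @return Object of class `vcg_grid`: `summary` data frame (family, params,
#'   sens, spec, acc, ppv, npv, f1, auc, fold accuracies), `predictions`
#'   (list of `fold_predictions`), `plan`, `labels`, `seed`.
#' @export
train_grid <- function(features, labels, seed = 1L, families = NULL, k = 10,
                       progress = FALSE) {
  configs <- enumerate_grid(families)
  plan <- make_folds(labels, k = k, seed = seed)
  preds <- vector("list", length(configs))
  rows <- vector("list", length(configs))
  last_fam <- ""
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    if (progress && cf$family != last_fam) {
      message("training family ", cf$family)
      last_fam <- cf$family
    }
    fp <- fit_predict_config(cf, features, labels, plan, seed = seed)
    preds[[i]] <- fp
    if (fp$supported) {
      cm <- confusion(labels, fp$labels_pred)
      mt <- metrics(cm)
      auc <- roc_auc(fp$scores, labels)$auc
      rows[[i]] <- data.frame(
        family = cf$family, params = config_label(cf), supported = TRUE,
        sens = mt$sens, spec = mt$spec, acc = mt$acc, ppv = mt$ppv,
        npv = mt$npv, f1 = mt$f1, auc = auc,
        fold_accs = paste(sprintf("%.4f", fp$per_fold_accuracy), collapse = ";"),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        family = cf$family, params = config_label(cf), supported = FALSE,
        sens = NA_real_, spec = NA_real_, acc = NA_real_, ppv = NA_real_,
        npv = NA_real_, f1 = NA_real_, auc = NA_real_, fold_accs = "",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), predictions = preds,
                 configs = configs, plan = plan,
                 labels = as.character(labels), seed = as.integer(seed)),
            class = "vcg_grid")
}

#' @export
print.vcg_grid <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<vcg_grid> %d configurations (%d supported), %d samples, %d-fold CV\n",
              nrow(s), sum(s$supported), length(x$labels), x$plan$k))
  b <- best_configs(x)
  cat("per-family best (by CV accuracy):\n")
  print(b[, c("family", "params", "acc", "sens", "spec", "auc")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.vcg_grid <- function(object, ...) object$summary

#' Per-family best configurations
#'
#' Selects, within each family, the supported configuration with the highest
#' cross-validated accuracy, breaking ties by higher sensitivity (then by
#' grid order).
#'
#' @param grid A `vcg_grid`.
#' @return The selected rows of `grid$summary`, with an `index` column
#'   pointing into `grid$predictions`.
#' @export
best_configs <- function(grid) {
  s <- grid$summary
  s$index <- seq_len(nrow(s))
  s <- s[s$supported, ]
  picks <- lapply(split(s, s$family), function(d) {
    d <- d[order(-d$acc, -d$sens, d$index), ]
    d[1, ]
  })
  out <- do.call(rbind, picks)
  fam_order <- unique(grid$summary$family)
  out <- out[order(match(out$family, fam_order)), ]
  rownames(out) <- NULL
  out
}

#' Out-of-fold score matrix for selected configurations
#'
#' Column j holds the OOF scores of configuration j; the per-column
#' no-leakage guarantee is inherited from [fit_predict_config()].
#'
#' @param selected List of `fold_predictions` (or a `vcg_grid` plus `index`).
#' @return Matrix samples x models, with the recorded `train_index_sets` of
#'   every column attached as attribute `train_index_sets`.
#' @export
build_oof_matrix <- function(selected) {
  if (!all(vapply(selected, inherits, TRUE, "fold_predictions")))
    stopf("selected must be a list of fold_predictions")
  if (any(!vapply(selected, `[[`, TRUE, "supported")))
    stopf("all selected configurations must be supported")
  m <- vapply(selected, `[[`, numeric(length(selected[[1]]$scores)), "scores")
  colnames(m) <- vapply(selected, function(p) p$config$family, "")
  attr(m, "train_index_sets") <- lapply(selected, `[[`, "train_index_sets")
  attr(m, "fold_of") <- selected[[1]]$fold_of
  m
}

#' Permutation importance of features
#'
#' For each feature column, the average (over `n_repeats` seeded shuffles) of
#' the increase in classification error when that column is randomly
#' permuted. Negative values are possible and indicate redundancy or noise.
#'
#' @param score_fn Function mapping a feature data frame/matrix to MI scores
#'   in `[0,1]`.
#' @param features Feature table (12 columns).
#' @param labels `"MI"`/`"HC"`.
#' @param n_repeats Shuffles per feature (>= 1).
#' @param seed Seed for the shuffles.
#' @return Named numeric vector of mean error increases per feature.
#' @export
permutation_importance <- function(score_fn, features, labels, n_repeats = 10,
                                   seed = 1L) {
  stopifnot(n_repeats >= 1)
  X <- as.data.frame(features)[, feature_names(), drop = FALSE]
  y <- as.character(labels)
  err <- function(scores) mean(ifelse(scores > 0.5, "MI", "HC") != y)
  base <- err(score_fn(X))
  with_seed(derive_seed(seed, "pif"), {
    vapply(feature_names(), function(fn) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[[fn]] <- sample(Xp[[fn]])
        err(score_fn(Xp))
      }, 0))
    }, 0) - base
  })
}
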