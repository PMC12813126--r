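#' Fit the stacking meta-classifier on out-of-fold base scores
#'
#' Decision-level fusion: the per-family best base configurations are
#' cross-validated on one shared stratified fold plan, their out-of-fold
#' scores form the meta-feature matrix, and a logistic regression
#' meta-classifier combines them. Stacking itself is evaluated leakage-free
#' by an outer pass over the same folds: for each fold the meta-classifier is
#' refitted on the OOF rows of the other nine folds and scores the held-out
#' fold.
#'
#' @param features Feature table (12 columns, plus optionally `record_id` /
#'   `label`).
#' @param labels `"MI"`/`"HC"` labels; defaults to the table's `label`
#'   column.
#' @param grid Optional precomputed [train_grid()] result (must carry the
#'   same labels); when absent the full grid is trained here.
#' @param seed Master seed (folds, stochastic learners).
#' @param k Folds.
#' @param families Families eligible as base models.
#' @return Object of class `vcg_stack` with the selected `base_configs`,
#'   the meta-coefficients, the OOF matrix, the stacked OOF `scores`,
#'   per-fold accuracies and the metric suite.
#' @export
vcg_stack <- function(features, labels = features$label, grid = NULL,
                      seed = 1L, k = 10, families = NULL) {
  labels <- as.character(labels)
  if (is.null(grid))
    grid <- train_grid(features, labels, seed = seed, families = families, k = k)
  if (!identical(grid$labels, labels))
    stopf("grid was trained on different labels")
  best <- best_configs(grid)
  preds <- grid$predictions[best$index]
  oof <- build_oof_matrix(preds)
  plan <- grid$plan
  fs <- fit_stacking(oof, labels, plan)
  scores <- fs$scores
  per_fold <- fs$per_fold_accuracy
  coefs <- fs$coefficients
  pred_lab <- ifelse(scores > 0.5, "MI", "HC")
  cm <- confusion(labels, pred_lab)
  structure(list(base_configs = lapply(preds, `[[`, "config"),
                 base_summary = best,
                 coefficients = coefs,
                 oof = oof,
                 scores = scores,
                 labels = labels,
                 labels_pred = pred_lab,
                 per_fold_accuracy = per_fold,
                 plan = plan,
                 confusion = cm,
                 metrics = metrics(cm),
                 roc = roc_auc(scores, labels),
                 seed = as.integer(seed)),
            class = "vcg_stack")
}

#' Fit the logistic meta-classifier on an out-of-fold score matrix
#'
#' The meta-classifier is trained on OOF base scores only. Its own
#' generalization is measured by an outer pass over the fold plan: for each
#' fold, the logistic combination is refitted on the OOF rows of the
#' remaining folds and scores the held-out fold, so the reported stacked
#' scores are themselves out-of-fold.
#'
#' @param oof_matrix Samples x models matrix of OOF base scores (>= 1
#'   column), e.g. from [build_oof_matrix()].
#' @param labels `"MI"`/`"HC"` labels.
#' @param plan The [make_folds()] plan the OOF scores were produced under.
#' @return List with `coefficients` (intercept + one weight per base model),
#'   `scores` (stacked OOF scores), `per_fold_accuracy`.
#' @export
fit_stacking <- function(oof_matrix, labels, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  oof <- as.matrix(oof_matrix)
  if (ncol(oof) < 1) stopf("oof_matrix needs >= 1 column")
  y01 <- as.integer(as.character(labels) == "MI")
  if (nrow(oof) != length(y01)) stopf("oof_matrix/labels length mismatch")
  logistic_fit <- function(rows) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, oof[rows, , drop = FALSE]),
                                           y01[rows],
                                           family = stats::binomial()))
    co <- fit$coefficients
    co[!is.finite(co)] <- 0
    co
  }
  scores <- numeric(length(y01))
  per_fold <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    tr <- which(plan$fold_of != f)
    te <- which(plan$fold_of == f)
    co <- logistic_fit(tr)
    scores[te] <- stats::plogis(as.numeric(cbind(1, oof[te, , drop = FALSE]) %*% co))
    per_fold[f] <- mean((scores[te] > 0.5) == (y01[te] == 1))
  }
  coefs <- logistic_fit(seq_along(y01))
  names(coefs) <- c("(Intercept)",
                    if (is.null(colnames(oof))) paste0("base", seq_len(ncol(oof)))
                    else colnames(oof))
  list(coefficients = coefs, scores = scores, per_fold_accuracy = per_fold)
}

#' Predict stacked MI scores from base-model scores
#'
#' @param object A `vcg_stack`.
#' @param base_scores Matrix (samples x base models) of base scores in the
#'   column order of `object$coefficients[-1]`.
#' @param ... Unused.
#' @return Numeric MI scores in `[0,1]`.
#' @export
predict.vcg_stack <- function(object, base_scores, ...) {
  base_scores <- as.matrix(base_scores)
  if (ncol(base_scores) != length(object$coefficients) - 1L)
    stopf("base_scores must have %d columns", length(object$coefficients) - 1L)
  stats::plogis(as.numeric(cbind(1, base_scores) %*% object$coefficients))
}

#' @export
coef.vcg_stack <- function(object, ...) object$coefficients

#' @export
print.vcg_stack <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<vcg_stack> %d base models, %d samples, %d-fold CV\n",
              length(x$base_configs), length(x$labels), x$plan$k))
  cat(sprintf("  stacked OOF: acc %.2f%%  sens %.2f%%  spec %.2f%%  AUC %.2f%%\n",
              100 * m$acc, 100 * m$sens, 100 * m$spec, 100 * x$roc$auc))
  invisible(x)
}

#' @export
summary.vcg_stack <- function(object, ...) {
  m <- object$metrics
  base <- object$base_summary[, c("family", "params", "acc", "sens", "spec", "auc")]
  cat("Base models (per-family best by CV accuracy):\n")
  print(base, row.names = FALSE, digits = 4)
  cat("\nMeta-classifier coefficients (logistic):\n")
  print(round(object$coefficients, 3))
  cat(sprintf(paste0("\nStacked out-of-fold performance: sens %.2f%%  spec %.2f%%",
                     "  acc %.2f%%  ppv %.2f%%  npv %.2f%%  f1 %.2f%%  AUC %.2f%%\n"),
              100 * m$sens, 100 * m$spec, 100 * m$acc, 100 * m$ppv,
              100 * m$npv, 100 * m$f1, 100 * object$roc$auc))
  invisible(object)
}
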