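#' Confusion matrix with MI as the positive class
#'
#' @param y_true,y_pred Equal-length vectors with values in `{"MI","HC"}`.
#' @return List of class `confusion_matrix` with integer counts `tp` (MI
#'   called MI), `fn` (MI called HC), `fp` (HC called MI), `tn` (HC called
#'   HC).
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  ok <- c("MI", "HC")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok))
    stopf("labels must be 'MI' or 'HC'")
  structure(list(tp = sum(y_true == "MI" & y_pred == "MI"),
                 fn = sum(y_true == "MI" & y_pred == "HC"),
                 fp = sum(y_true == "HC" & y_pred == "MI"),
                 tn = sum(y_true == "HC" & y_pred == "HC")),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp, fn, fp, tn)
  if (any(v < 0) || any(v != round(v))) stopf("counts must be non-negative integers")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("MI", "HC"), predicted = c("MI", "HC")))
  print(m)
  invisible(x)
}

#' Classification metric suite from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, accuracy and f1 (harmonic mean of PPV and
#' sensitivity). A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param cm A `confusion_matrix`.
#' @return List of class `metric_report` with fractions in `[0,1]`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(cm$tp, cm$tp + cm$fn)
  spec <- frac(cm$tn, cm$tn + cm$fp)
  ppv <- frac(cm$tp, cm$tp + cm$fp)
  npv <- frac(cm$tn, cm$tn + cm$fn)
  acc <- frac(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  structure(list(sens = sens, spec = spec, acc = acc, ppv = ppv, npv = npv,
                 f1 = f1), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("sens %s  spec %s  acc %s  ppv %s  npv %s  f1 %s\n",
              pct(x$sens), pct(x$spec), pct(x$acc), pct(x$ppv), pct(x$npv),
              pct(x$f1)))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores (classifying MI
#' when score >= threshold), yielding a non-decreasing (fpr, tpr) polyline;
#' AUC by the trapezoid rule, which handles tied scores as midpoints and so
#' equals the Mann-Whitney rank statistic `U/(n1*n2)` on the scores.
#'
#' @param scores Numeric MI scores (higher = more MI-like).
#' @param y_true `"MI"`/`"HC"` labels (both classes present).
#' @return List of class `roc_curve`: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y <- as.character(y_true)
  if (!all(c("MI", "HC") %in% y)) stopf("both classes must be present")
  if (length(scores) != length(y)) stopf("length mismatch")
  n1 <- sum(y == "MI"); n0 <- sum(y == "HC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == "MI") / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == "HC") / n0, 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cp <- cut_point(x)
  cat(sprintf("<roc_curve> %d thresholds, AUC %.4f; cut-point fpr %.3f tpr %.3f (thr %.4g)\n",
              length(x$thresholds), x$auc, cp$fpr, cp$tpr, cp$threshold))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  cp <- cut_point(x)
  graphics::points(cp$fpr, cp$tpr, pch = 19)
  invisible(x)
}

#' Operating cut-point of a ROC curve
#'
#' The vertex maximizing the Youden index `J = tpr - fpr`; ties broken
#' toward higher tpr (favoring sensitivity). Alternatively the vertex
#' closest to the ideal corner (0, 1).
#'
#' @param curve A `roc_curve`.
#' @param criterion `"youden"` (default) or `"closest"`.
#' @return List `fpr`, `tpr`, `threshold`.
#' @export
cut_point <- function(curve, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_curve"))
  score <- if (criterion == "youden") curve$tpr - curve$fpr
           else -sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  best <- which(score >= max(score) - 1e-12)
  best <- best[which.max(curve$tpr[best])]
  list(fpr = curve$fpr[best], tpr = curve$tpr[best],
       threshold = curve$thresholds[best])
}

#' Machine-readable evaluation report
#'
#' Serializes per-model metric reports (and optionally the stack) as
#' canonical JSON plus a summary CSV with deterministic ordering, so two
#' runs on identical inputs produce byte-identical artifacts.
#'
#' @param model_metrics Named list: each element a list with at least
#'   `metrics` (a `metric_report`), optionally `auc`, `per_fold_accuracy`,
#'   `confusion` (a `confusion_matrix`).
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @param meta Named list appended verbatim (seed, config hash, ...).
#' @return The report structure, invisibly.
#' @export
write_report <- function(model_metrics, json_path = NULL, csv_path = NULL,
                         meta = list()) {
  if (length(model_metrics))
    model_metrics <- model_metrics[order(names(model_metrics))]
  payload <- list(models = lapply(model_metrics, function(mm) {
    out <- list(metrics = unclass(mm$metrics))
    if (!is.null(mm$auc)) out$auc <- mm$auc
    if (!is.null(mm$per_fold_accuracy)) out$per_fold_accuracy <- mm$per_fold_accuracy
    if (!is.null(mm$confusion)) out$confusion <- unclass(mm$confusion)
    out
  }), meta = meta)
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    rows <- lapply(names(model_metrics), function(nm) {
      m <- model_metrics[[nm]]$metrics
      data.frame(model = nm, sens = m$sens, spec = m$spec, acc = m$acc,
                 ppv = m$ppv, npv = m$npv, f1 = m$f1,
                 auc = if (is.null(model_metrics[[nm]]$auc)) NA_real_
                       else model_metrics[[nm]]$auc)
    })
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(payload)
}
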