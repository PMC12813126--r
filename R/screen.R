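#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper around [stats::shapiro.test()] with the sample-size contract
#' made explicit (3 <= n <= 5000).
#'
#' @param values Numeric vector.
#' @return p-value.
#' @export
shapiro_wilk_p <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(values))
  stats::shapiro.test(values)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Returns the U statistic for `group_a` and a two-sided p-value. The exact
#' null distribution (full enumeration) is used when `n_a * n_b <= 400` and
#' the pooled sample is tie-free; otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"approximate"`).
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # fully tied samples: zero-variance null, no evidence
  list(U = unname(wt$statistic), p = min(1, p),
       method = if (exact) "exact" else "approximate")
}

#' Screen the feature table: normality check and Mann-Whitney ranking
#'
#' For every feature, computes the pooled-sample Shapiro-Wilk p-value (with
#' per-class values alongside) and the two-sided Mann-Whitney p-value between
#' the MI and HC groups, then ranks features by ascending Mann-Whitney p
#' (ties broken by feature name). No feature is ever dropped: screening is
#' diagnostic only and the feature table passes downstream unchanged.
#'
#' @param feature_table Data frame from [cohort_features()] /
#'   [read_feature_table()], or a plain matrix/data frame of the 12 features.
#' @param labels Class labels (`"MI"`/`"HC"`); defaults to the table's
#'   `label` column.
#' @return Data frame of class `screen_result` ordered by ascending
#'   Mann-Whitney p, with columns `feature`, `sw_p`, `sw_p_mi`, `sw_p_hc`,
#'   `mw_u`, `mw_p`, `rank`.
#' @export
screen_features <- function(feature_table, labels = feature_table$label) {
  labels <- as.character(labels)
  if (!all(c("MI", "HC") %in% labels)) stopf("both classes must be present")
  fm <- as.data.frame(feature_table)[, feature_names(), drop = FALSE]
  rows <- lapply(feature_names(), function(fn) {
    v <- fm[[fn]]
    mw <- mann_whitney(v[labels == "MI"], v[labels == "HC"])
    sw_safe <- function(x) if (stats::sd(x) < 1e-12) NA_real_ else shapiro_wilk_p(x)
    data.frame(feature = fn,
               sw_p = sw_safe(v),
               sw_p_mi = sw_safe(v[labels == "MI"]),
               sw_p_hc = sw_safe(v[labels == "HC"]),
               mw_u = mw$U, mw_p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mw_p, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Feature screen (sorted by Mann-Whitney p, all features retained):\n")
  y <- as.data.frame(x)
  y$sw_p <- signif(y$sw_p, 3); y$mw_p <- signif(y$mw_p, 3)
  print(y[, c("rank", "feature", "sw_p", "mw_p")], row.names = FALSE)
  invisible(x)
}

#' Five-number boxplot summary with Tukey outliers retained
#'
#' Quartiles use linear interpolation (quantile type 7); outliers are values
#' beyond 1.5 IQR of the quartiles. Outliers are listed, never removed: the
#' screen treats them as genuine clinical observations.
#'
#' @param values Numeric vector, n >= 1.
#' @return List `min`, `q1`, `median`, `q3`, `max`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 1) stopf("boxplot_summary needs n >= 1")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
  list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       outliers = out)
}
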