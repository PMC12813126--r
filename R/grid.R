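#' Enumerate the 210-configuration classifier grid
#'
#' Reproduces the full hyperparameter grid of the nine classifier families:
#' SVM (5 kernels x 5 kernel scales), discriminant analysis (6 variants),
#' KNN (4 neighborhood sizes x 3 distances x 3 vote weightings), decision
#' tree (2 split criteria x 4 minimum leaf sizes x 4 split caps), neural
#' network (16 two-layer + 4 one-layer sizes), naive Bayes (10
#' prior/distribution/kernel rows), random forest (5 tree counts x 5 leaf
#' sizes), logistic regression (2 priors x 2 penalties x 6 solvers, with the
#' solver/penalty combinations that are not supported enumerated but
#' flagged), and ensemble methods (32 boosting rows). Total: 210.
#'
#' @param families Optional character subset of
#'   `c("SVM","DA","KNN","DT","ANN","NB","RF","LR","EM")`.
#' @return List of `classifier_config` objects, in stable family/row order.
#' @export
enumerate_grid <- function(families = NULL) {
  cfg <- function(family, supported = TRUE, ...) {
    params <- list(...)
    structure(list(family = family, params = params, supported = supported,
                   id = paste(family, paste(unlist(params), collapse = "/"),
                              sep = ":")),
              class = "classifier_config")
  }
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x

  for (kernel in c("poly2", "poly3", "poly4", "linear", "rbf"))
    for (scale in 1:5) add(cfg("SVM", kernel = kernel, scale = scale))

  for (type in c("linear", "diag_linear", "pseudo_linear",
                 "quadratic", "diag_quadratic", "pseudo_quadratic"))
    add(cfg("DA", type = type))

  for (k in c(5, 10, 15, 20))
    for (distance in c("euclidean", "cityblock", "chebyshev"))
      for (weight in c("equal", "inverse", "squared_inverse"))
        add(cfg("KNN", k = k, distance = distance, weight = weight))

  for (criterion in c("gdi", "crossentropy"))
    for (min_leaf in c(2, 4, 8, 16))
      for (max_splits in c(5, 10, 20, 50))
        add(cfg("DT", criterion = criterion, min_leaf = min_leaf,
                max_splits = max_splits))

  for (s1 in c(5, 10, 20, 50))
    for (s2 in c(5, 10, 20, 50))
      add(cfg("ANN", layers = 2, size1 = s1, size2 = s2))
  for (s1 in c(5, 10, 20, 50)) add(cfg("ANN", layers = 1, size1 = s1))

  for (prior in c("uniform", "empirical")) {
    add(cfg("NB", prior = prior, distribution = "normal"))
    for (kt in c("normal", "box", "epanechnikov", "triangle"))
      add(cfg("NB", prior = prior, distribution = "kernel", kernel = kt))
  }

  for (ntrees in c(100, 200, 300, 400, 500))
    for (min_leaf in 1:5) add(cfg("RF", ntrees = ntrees, min_leaf = min_leaf))

  lr_supported <- list(
    uniform = list(lasso = c("sgd", "sparsa"), ridge = c("sgd", "bfgs", "lbfgs")),
    empirical = list(lasso = "sparsa", ridge = c("bfgs", "lbfgs")))
  for (prior in c("uniform", "empirical"))
    for (reg in c("lasso", "ridge"))
      for (solver in c("sgd", "asgd", "dual", "bfgs", "lbfgs", "sparsa"))
        add(cfg("LR", supported = solver %in% lr_supported[[prior]][[reg]],
                prior = prior, regularization = reg, solver = solver))

  for (method in c("adaboost", "robustboost", "rusboost"))
    for (learner in c("tree", "discriminant"))
      for (cycles in c(50, 100, 150, 200))
        add(cfg("EM", method = method, learner = learner, cycles = cycles))
  for (method in c("logitboost", "gentleboost"))
    for (cycles in c(50, 100, 150, 200))
      add(cfg("EM", method = method, learner = "tree", cycles = cycles))

  if (!is.null(families)) {
    fams <- vapply(out, `[[`, "", "family")
    bad <- setdiff(families, unique(fams))
    if (length(bad)) stopf("unknown family: %s", paste(bad, collapse = ", "))
    out <- out[fams %in% families]
  }
  out
}

#' @export
print.classifier_config <- function(x, ...) {
  cat(sprintf("<classifier_config> %s%s\n", x$id,
              if (x$supported) "" else " (unsupported)"))
  invisible(x)
}

#' Canonical one-line text form of a configuration's parameters
#' @param config A `classifier_config`.
#' @return Character scalar like `"kernel=poly3 scale=1"`.
#' @export
config_label <- function(config) {
  paste(names(config$params), unlist(config$params), sep = "=", collapse = " ")
}

#' Stratified k-fold plan
#'
#' Partitions samples into `k` folds so that per-fold class counts differ
#' from perfect stratification by at most one. Deterministic for a fixed
#' seed.
#'
#' @param labels Class labels (any two-level vector).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of class `fold_plan`: `fold_of` (fold id 1..k per sample),
#'   `k`, `seed`.
#' @export
make_folds <- function(labels, k = 10, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) stopf("each class needs >= k members (k=%d, counts: %s)",
                          k, paste(tab, collapse = ", "))
  fold_of <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  structure(list(fold_of = fold_of, k = k, seed = as.integer(seed)),
            class = "fold_plan")
}
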