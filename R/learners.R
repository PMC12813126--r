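# Internal base-learner layer: every family exposes fit(X, y01) -> model and
# score(model, X) -> MI probability in [0, 1]. X is an already-standardized
# numeric matrix; y01 is 1 for MI, 0 for HC. Established packages back the
# families they cover (rpart, e1071, randomForest, glmnet); KNN with the
# non-Euclidean distances and vote weights, the six-variant Gaussian
# discriminant, kernel-density naive Bayes, the 1-2 hidden-layer MLP and the
# boosting engine are implemented here because no installed package provides
# them with the required options.

fit_learner <- function(config, X, y01, seed) {
  if (!config$supported)
    stopf("configuration %s is not supported", config$id)
  p <- config$params
  with_seed(seed, switch(config$family,
    SVM = fit_svm(X, y01, p$kernel, p$scale),
    DA  = fit_gda(X, y01, p$type),
    KNN = list(kind = "knn", X = X, y = y01, k = p$k,
               distance = p$distance, weight = p$weight),
    DT  = fit_dt(X, y01, p$criterion, p$min_leaf, p$max_splits),
    ANN = fit_mlp(X, y01, sizes = if (p$layers == 2) c(p$size1, p$size2)
                  else p$size1),
    NB  = fit_nbk(X, y01, p$prior, p$distribution,
                  if (is.null(p$kernel)) "normal" else p$kernel),
    RF  = list(kind = "rf",
               fit = randomForest::randomForest(
                 x = X, y = factor(y01, levels = c(0, 1)),
                 ntree = p$ntrees, nodesize = p$min_leaf)),
    LR  = fit_lrn(X, y01, p$prior, p$regularization),
    EM  = fit_boost(X, y01, p$method, p$learner, p$cycles),
    stopf("unknown family %s", config$family)))
}

score_learner <- function(model, X) {
  s <- switch(model$kind,
    svm = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    gda = score_gda(model, X),
    knn = score_knn(model, X),
    dt = stats::predict(model$fit, as.data.frame(X), type = "prob")[, "1"],
    mlp = mlp_forward(model$par, model$sizes, ncol(X), X)$p,
    nbk = score_nbk(model, X),
    rf = stats::predict(model$fit, X, type = "prob")[, "1"],
    lrn = as.numeric(stats::predict(model$fit, X, type = "response",
                                    s = model$lambda)),
    boost = stats::plogis(2 * boost_margin(model, X)),
    stopf("unknown model kind %s", model$kind))
  pmin(1, pmax(0, as.numeric(s)))
}

# ---- SVM (e1071) ------------------------------------------------------------
# Kernel scale s enters as in K((x/s), (y/s)): gamma = 1/s^2; polynomial
# kernels use offset 1, the scaled linear kernel is polynomial of degree 1
# with offset 0.
fit_svm <- function(X, y01, kernel, scale) {
  g <- 1 / scale^2
  args <- switch(kernel,
    poly2 = list(kernel = "polynomial", degree = 2, gamma = g, coef0 = 1),
    poly3 = list(kernel = "polynomial", degree = 3, gamma = g, coef0 = 1),
    poly4 = list(kernel = "polynomial", degree = 4, gamma = g, coef0 = 1),
    linear = list(kernel = "polynomial", degree = 1, gamma = g, coef0 = 0),
    rbf = list(kernel = "radial", gamma = g),
    stopf("unknown SVM kernel %s", kernel))
  fit <- do.call(e1071::svm, c(list(
    x = X, y = factor(y01, levels = c(0, 1)), scale = FALSE,
    probability = TRUE, cost = 1), args))
  list(kind = "svm", fit = fit)
}

# ---- Decision tree (rpart, pruned to the split cap) -------------------------
fit_dt <- function(X, y01, criterion, min_leaf, max_splits) {
  df <- data.frame(X, y = factor(y01, levels = c(0, 1)))
  split <- if (criterion == "gdi") "gini" else "information"
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      parms = list(split = split),
                      control = rpart::rpart.control(
                        minbucket = min_leaf, minsplit = max(2, 2 * min_leaf),
                        cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0))
  ct <- fit$cptable
  ok <- which(ct[, "nsplit"] <= max_splits)
  row <- ok[which.max(ct[ok, "nsplit"])]
  if (ct[row, "nsplit"] < max(ct[, "nsplit"]))
    fit <- rpart::prune(fit, cp = ct[row, "CP"] * 1.0000001)
  list(kind = "dt", fit = fit)
}

# ---- KNN with configurable distance and vote weighting ----------------------
knn_dist <- function(A, B, distance) {
  # rows of A (test) vs rows of B (train)
  switch(distance,
    euclidean = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      D <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A)))
        D <- D + abs(outer(A[, j], B[, j], "-"))
      D
    },
    chebyshev = {
      D <- matrix(-Inf, nrow(A), nrow(B))
      for (j in seq_len(ncol(A)))
        D <- pmax(D, abs(outer(A[, j], B[, j], "-")))
      D
    },
    stopf("unknown KNN distance %s", distance))
}

score_knn <- function(model, X) {
  D <- knn_dist(as.matrix(X), model$X, model$distance)
  k <- min(model$k, ncol(D))
  eps <- 1e-9
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    w <- switch(model$weight,
                equal = rep(1, k),
                inverse = 1 / (d[nn] + eps),
                squared_inverse = 1 / (d[nn] + eps)^2)
    sum(w * model$y[nn]) / sum(w)
  })
}

# ---- Gaussian discriminant analysis (6 variants) ----------------------------
# linear: pooled covariance; quadratic: per-class; diag_*: diagonalized;
# pseudo_*: Moore-Penrose pseudo-inverse with pseudo-log-determinant.
fit_gda <- function(X, y01, type) {
  cls <- c(0, 1)
  n <- nrow(X)
  mu <- lapply(cls, function(c) colMeans(X[y01 == c, , drop = FALSE]))
  prior <- vapply(cls, function(c) mean(y01 == c), 0)
  covs <- lapply(cls, function(c) {
    Xi <- X[y01 == c, , drop = FALSE]
    crossprod(sweep(Xi, 2, colMeans(Xi))) / max(1, nrow(Xi) - 1)
  })
  pooled <- grepl("linear", type)
  if (pooled) {
    ns <- vapply(cls, function(c) sum(y01 == c), 0)
    S <- (covs[[1]] * (ns[1] - 1) + covs[[2]] * (ns[2] - 1)) / (n - 2)
    covs <- list(S, S)
  }
  if (grepl("^diag", type)) covs <- lapply(covs, function(S) diag(diag(S)))
  inv_logdet <- function(S) {
    if (grepl("^pseudo", type)) {
      e <- eigen(S, symmetric = TRUE)
      keep <- e$values > max(e$values) * 1e-10
      inv <- e$vectors[, keep, drop = FALSE] %*%
        (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
      list(inv = inv, logdet = sum(log(e$values[keep])))
    } else {
      S <- S + diag(1e-10 * mean(diag(S)), ncol(S))
      ch <- chol(S)
      list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
    }
  }
  il <- lapply(covs, inv_logdet)
  list(kind = "gda", mu = mu, prior = prior, il = il)
}

score_gda <- function(model, X) {
  X <- as.matrix(X)
  lp <- vapply(1:2, function(c) {
    d <- sweep(X, 2, model$mu[[c]])
    -0.5 * rowSums((d %*% model$il[[c]]$inv) * d) -
      0.5 * model$il[[c]]$logdet + log(model$prior[c])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) lp <- matrix(lp, nrow = 1)
  1 / (1 + exp(lp[, 1] - lp[, 2]))
}

# ---- MLP with 1 or 2 tanh hidden layers, L-BFGS training --------------------
mlp_npar <- function(sizes, d) {
  dims <- c(d, sizes, 1)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

mlp_unpack <- function(par, sizes, d) {
  dims <- c(d, sizes, 1)
  W <- list(); b <- list(); off <- 0
  for (l in seq_len(length(dims) - 1)) {
    nw <- dims[l] * dims[l + 1]
    W[[l]] <- matrix(par[off + seq_len(nw)], dims[l], dims[l + 1]); off <- off + nw
    b[[l]] <- par[off + seq_len(dims[l + 1])]; off <- off + dims[l + 1]
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, sizes, d, X) {
  wb <- mlp_unpack(par, sizes, d)
  a <- list(as.matrix(X))
  L <- length(wb$W)
  for (l in seq_len(L - 1))
    a[[l + 1]] <- tanh(sweep(a[[l]] %*% wb$W[[l]], 2, wb$b[[l]], "+"))
  z <- as.numeric(a[[L]] %*% wb$W[[L]] + wb$b[[L]])
  list(p = stats::plogis(z), a = a, wb = wb)
}

fit_mlp <- function(X, y01, sizes, maxit = 300, l2 = 1e-4) {
  d <- ncol(X); n <- nrow(X)
  np <- mlp_npar(sizes, d)
  dims <- c(d, sizes, 1)
  init <- stats::rnorm(np, sd = rep(1 / sqrt(dims[-length(dims)]),
                                    dims[-length(dims)] * dims[-1] + dims[-1]))
  loss <- function(par) {
    fw <- mlp_forward(par, sizes, d, X)
    p <- pmin(1 - 1e-12, pmax(1e-12, fw$p))
    -mean(y01 * log(p) + (1 - y01) * log(1 - p)) + l2 * sum(par^2) / 2
  }
  grad <- function(par) {
    fw <- mlp_forward(par, sizes, d, X)
    wb <- fw$wb; a <- fw$a; L <- length(wb$W)
    delta <- matrix((fw$p - y01) / n, ncol = 1)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- t(a[[l]]) %*% delta
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(wb$W[[l]])) * (1 - a[[l]]^2)
    }
    g <- numeric(0)
    for (l in seq_len(L)) g <- c(g, as.numeric(gW[[l]]), gb[[l]])
    g + l2 * par
  }
  opt <- stats::optim(init, loss, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(kind = "mlp", par = opt$par, sizes = sizes)
}

# ---- Kernel-density naive Bayes ---------------------------------------------
fit_nbk <- function(X, y01, prior, distribution, kernel) {
  kmap <- c(normal = "gaussian", box = "rectangular",
            epanechnikov = "epanechnikov", triangle = "triangular")
  pr <- if (prior == "uniform") c(0.5, 0.5)
        else c(mean(y01 == 0), mean(y01 == 1))
  dens <- lapply(c(0, 1), function(cl) {
    lapply(seq_len(ncol(X)), function(j) {
      v <- X[y01 == cl, j]
      if (distribution == "normal" || length(unique(v)) < 2) {
        list(type = "gauss", mean = mean(v), sd = max(stats::sd(v), 1e-6))
      } else {
        d <- stats::density(v, kernel = kmap[[kernel]], n = 512,
                            cut = 3)
        list(type = "kde", x = d$x, y = d$y)
      }
    })
  })
  list(kind = "nbk", prior = pr, dens = dens)
}

score_nbk <- function(model, X) {
  X <- as.matrix(X)
  ll <- vapply(1:2, function(c) {
    s <- log(model$prior[c]) + numeric(nrow(X))
    for (j in seq_len(ncol(X))) {
      dj <- model$dens[[c]][[j]]
      f <- if (dj$type == "gauss")
        stats::dnorm(X[, j], dj$mean, dj$sd)
      else
        stats::approx(dj$x, dj$y, xout = X[, j], yleft = 0, yright = 0)$y
      s <- s + log(pmax(f, 1e-12))
    }
    s
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) ll <- matrix(ll, nrow = 1)
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

# ---- Penalized logistic regression (glmnet) ---------------------------------
# The solver is a row label: all supported solvers reach the same penalized
# optimum, computed here by coordinate descent. Prior "uniform" balances the
# classes through observation weights.
fit_lrn <- function(X, y01, prior, regularization, lambda = 0.01) {
  w <- if (prior == "uniform") {
    n <- length(y01)
    ifelse(y01 == 1, n / (2 * sum(y01 == 1)), n / (2 * sum(y01 == 0)))
  } else rep(1, length(y01))
  fit <- glmnet::glmnet(X, y01, family = "binomial", weights = w,
                        alpha = if (regularization == "lasso") 1 else 0,
                        lambda = c(0.1, lambda), standardize = FALSE)
  list(kind = "lrn", fit = fit, lambda = lambda)
}

# ---- Boosting engine --------------------------------------------------------
# Weak learners: classification stump (exhaustive weighted threshold search),
# weighted pooled-covariance LDA, and a regression stump for the
# Newton/gradient variants. Margins accumulate in F; scores are
# plogis(2 * F).

stump_fit <- function(X, ypm, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xo <- X[o, j]; yo <- ypm[o]; wo <- w[o]
    # err(theta) for rule +1 if x > theta: misclassified = pos left + neg right
    pos_left <- cumsum(wo * (yo > 0))
    neg_left <- cumsum(wo * (yo < 0))
    tot_neg <- neg_left[length(neg_left)]
    err_gt <- pos_left + (tot_neg - neg_left)      # threshold after position i
    cand <- which(diff(xo) > 0)
    if (!length(cand)) next
    errs <- err_gt[cand]
    flip <- sum(w) - errs                          # polarity -1
    e1 <- min(errs); e2 <- min(flip)
    if (e1 <= e2 && e1 < best$err) {
      i <- cand[which.min(errs)]
      best <- list(err = e1, j = j, thr = (xo[i] + xo[i + 1]) / 2, pol = 1)
    } else if (e2 < e1 && e2 < best$err) {
      i <- cand[which.min(flip)]
      best <- list(err = e2, j = j, thr = (xo[i] + xo[i + 1]) / 2, pol = -1)
    }
  }
  if (!is.finite(best$err))
    best <- list(err = sum(w * (ypm > 0)), j = 1L, thr = Inf, pol = 1)
  best$kind <- "stump"
  best
}

stump_predict <- function(h, X)
  h$pol * ifelse(X[, h$j] > h$thr, 1, -1)

wlda_fit <- function(X, ypm, w) {
  w <- w / sum(w)
  i1 <- ypm > 0; i0 <- !i1
  if (!any(i1) || !any(i0)) return(stump_fit(X, ypm, w))
  m1 <- colSums(X[i1, , drop = FALSE] * w[i1]) / sum(w[i1])
  m0 <- colSums(X[i0, , drop = FALSE] * w[i0]) / sum(w[i0])
  Xc <- X - rbind(m0, m1)[ypm / 2 + 1.5, ]
  S <- crossprod(Xc * sqrt(w)) + diag(1e-6, ncol(X))
  beta <- solve(S, m1 - m0)
  thr <- sum(beta * (m1 + m0)) / 2 - log(sum(w[i1]) / sum(w[i0]))
  list(kind = "wlda", beta = beta, thr = thr)
}

wlda_predict <- function(h, X)
  ifelse(as.numeric(X %*% h$beta) > h$thr, 1, -1)

reg_stump_fit <- function(X, z, w) {
  sw <- sum(w)
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xo <- X[o, j]; zo <- z[o]; wo <- w[o]
    cw <- cumsum(wo); cwz <- cumsum(wo * zo); cwz2 <- cumsum(wo * zo^2)
    tw <- cw[length(cw)]; twz <- cwz[length(cwz)]; twz2 <- cwz2[length(cwz2)]
    cand <- which(diff(xo) > 0)
    if (!length(cand)) next
    lw <- cw[cand]; lz <- cwz[cand]
    rw <- tw - lw; rz <- twz - lz
    sse <- (twz2) - lz^2 / lw - rz^2 / pmax(rw, 1e-300)
    i <- which.min(sse)
    if (sse[i] < best$sse)
      best <- list(sse = sse[i], j = j, thr = (xo[cand[i]] + xo[cand[i] + 1]) / 2,
                   left = lz[i] / lw[i], right = rz[i] / rw[i])
  }
  if (!is.finite(best$sse))
    best <- list(sse = Inf, j = 1L, thr = Inf,
                 left = sum(w * z) / sw, right = sum(w * z) / sw)
  best$kind <- "rstump"
  best
}

reg_stump_predict <- function(h, X)
  ifelse(X[, h$j] > h$thr, h$right, h$left)

weak_fit <- function(learner, X, ypm, w)
  if (learner == "tree") stump_fit(X, ypm, w) else wlda_fit(X, ypm, w)

weak_predict <- function(h, X)
  if (h$kind == "stump") stump_predict(h, X) else wlda_predict(h, X)

fit_boost <- function(X, y01, method, learner, cycles) {
  ypm <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  hs <- list(); alphas <- numeric(0)
  Fm <- numeric(n)
  w <- rep(1 / n, n)
  for (m in seq_len(cycles)) {
    if (method == "logitboost") {
      p <- stats::plogis(2 * Fm)
      pw <- pmax(p * (1 - p), 1e-6)
      z <- pmax(-4, pmin(4, (y01 - p) / pw))
      h <- reg_stump_fit(X, z, pw / sum(pw))
      hs[[m]] <- h; alphas[m] <- 0.5
      Fm <- Fm + 0.5 * reg_stump_predict(h, X)
      next
    }
    if (method == "gentleboost") {
      wg <- exp(pmin(30, -ypm * Fm)); wg <- wg / sum(wg)
      h <- reg_stump_fit(X, ypm, wg)
      hs[[m]] <- h; alphas[m] <- 1
      Fm <- Fm + reg_stump_predict(h, X)
      next
    }
    wm <- switch(method,
      adaboost = w,
      robustboost = { v <- stats::plogis(-ypm * Fm); v / sum(v) },
      rusboost = w,
      stopf("unknown boosting method %s", method))
    if (method == "rusboost") {
      # balance classes: keep all minority samples, weight-sample the majority
      n1 <- sum(ypm > 0); n0 <- n - n1
      minority <- if (n1 <= n0) which(ypm > 0) else which(ypm < 0)
      majority <- setdiff(seq_len(n), minority)
      take <- sample(majority, size = min(length(minority), length(majority)),
                     prob = wm[majority] + 1e-12)
      sub <- c(minority, take)
      h <- weak_fit(learner, X[sub, , drop = FALSE], ypm[sub],
                    wm[sub] / sum(wm[sub]))
    } else {
      h <- weak_fit(learner, X, ypm, wm)
    }
    pred <- weak_predict(h, X)
    err <- sum(wm * (pred != ypm)) / sum(wm)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    hs[[length(hs) + 1L]] <- h
    alphas[length(alphas) + 1L] <- alpha
    Fm <- Fm + alpha * pred
    if (method %in% c("adaboost", "rusboost")) {
      w <- w * exp(-alpha * ypm * pred)
      w <- w / sum(w)
    }
    if (err <= 1e-9) break
  }
  if (length(hs) == 0L) {                 # no usable weak learner: prior only
    hs <- list(list(kind = "rstump", j = 1L, thr = Inf,
                    left = mean(ypm), right = mean(ypm)))
    alphas <- 1
  }
  list(kind = "boost", hs = hs, alphas = alphas, method = method)
}

boost_margin <- function(model, X) {
  X <- as.matrix(X)
  Fm <- numeric(nrow(X))
  for (m in seq_along(model$hs)) {
    h <- model$hs[[m]]
    Fm <- Fm + model$alphas[m] *
      (if (h$kind == "rstump") reg_stump_predict(h, X) else weak_predict(h, X))
  }
  Fm
}
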