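# Calibration algorithms. PLSR is first-party (NIPALS) because rank
# selection, loadings and VIP depend on its internals. The radial-kernel
# SVM is a least-squares SVM (kernel ridge with intercept, closed-form
# solve) and the random forest is a bagged regression-tree ensemble with
# random feature subsetting; all three share one fit/predict contract.

as_X <- function(spectra) {
  if (inherits(spectra, "spectra_set")) spectra$reflectance else
    as.matrix(spectra)
}

#' Fit a partial least squares regression
#'
#' Mean-centred univariate-response NIPALS. Weights, loadings and the
#' regression vector for every rank up to `n_components` are stored, so a
#' fitted model can predict at any rank and feed VIP importance.
#'
#' @param X predictor matrix (rows = samples, columns = wavelengths).
#' @param y numeric response (starch, % fresh mass).
#' @param n_components maximum number of latent variables.
#' @return a `calibration_model` with `algorithm = "PLSR"`.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- as_X(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y disagree on length", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: nothing to fit",
                              call. = FALSE)
  n_components <- min(n_components, n - 1L, p)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  W <- P <- matrix(0, p, n_components)
  q <- tt <- ssy <- numeric(n_components)
  Tsc <- matrix(0, n, n_components)
  A <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xc %*% w
    tt_a <- sum(t_^2)
    if (tt_a < 1e-12) break
    p_ <- crossprod(Xc, t_) / tt_a
    q_a <- sum(yc * t_) / tt_a
    Xc <- Xc - t_ %*% t(p_)
    yc <- yc - q_a * t_
    A <- a
    W[, a] <- w; P[, a] <- p_; q[a] <- q_a
    Tsc[, a] <- t_; tt[a] <- tt_a
    ssy[a] <- q_a^2 * tt_a
  }
  if (A == 0L) stop("no PLS component could be extracted", call. = FALSE)
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  coefs <- matrix(0, p, A)
  for (a in seq_len(A)) {
    coefs[, a] <- W[, seq_len(a), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(a), drop = FALSE],
                      W[, seq_len(a), drop = FALSE]),
            q[seq_len(a)])
  }
  structure(list(
    algorithm = "PLSR",
    wavelengths = colnames(X),
    x_center = x_center, y_center = y_center,
    W = W, P = P, q = q[seq_len(A)],
    scores = Tsc[, seq_len(A), drop = FALSE],
    tt = tt[seq_len(A)], ssy = ssy[seq_len(A)],
    coefficients = coefs,
    rank = A,
    hyperparams = list(n_components = A)
  ), class = "calibration_model")
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a radial-kernel least-squares SVM regression
#'
#' Kernel ridge regression with an intercept (the least-squares SVM dual):
#' solve `[0 1'; 1 K + I/cost] [b; alpha] = [0; y]` with
#' `K = exp(-gamma * ||x_i - x_j||^2)`. Predictors are standardised
#' internally.
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param cost regularisation cost C (larger = less ridge shrinkage).
#' @param gamma kernel width; default `1 / (p * mean column variance)`.
#' @return a `calibration_model` with `algorithm = "SVM_RADIAL"`.
#' @export
fit_svm_radial <- function(X, y, cost = 10, gamma = NULL) {
  X <- as_X(X)
  y <- as.numeric(y)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (is.null(gamma)) gamma <- 1 / (ncol(Xs) * max(mean(apply(Xs, 2,
    stats::var)), 1e-12))
  n <- nrow(Xs)
  K <- rbf_kernel(Xs, Xs, gamma)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / cost))
  sol <- solve(M, c(0, y))
  structure(list(
    algorithm = "SVM_RADIAL",
    wavelengths = colnames(X),
    x_center = ctr, x_scale = scl,
    X_train = Xs, alpha = sol[-1L], b = sol[1L],
    hyperparams = list(cost = cost, gamma = gamma)
  ), class = "calibration_model")
}

rf_best_split <- function(x, y, min_node) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cs <- cumsum(ys); css <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  valid <- i >= min_node & (n - i) >= min_node & xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- sse_l + sse_r
  tot[!valid] <- Inf
  best <- which.min(tot)
  list(threshold = (xs[best] + xs[best + 1L]) / 2,
       sse = tot[best])
}

rf_build <- function(X, y, idx, mtry, min_node, depth, max_depth) {
  yy <- y[idx]
  if (length(idx) < 2L * min_node || depth >= max_depth ||
      stats::var(yy) < 1e-12) {
    return(list(leaf = TRUE, value = mean(yy)))
  }
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  sse0 <- sum((yy - mean(yy))^2)
  for (f in feats) {
    sp <- rf_best_split(X[idx, f], yy, min_node)
    if (!is.null(sp) && sp$sse < sse0 - 1e-12 &&
        (is.null(best) || sp$sse < best$sse)) {
      best <- c(sp, feat = f)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(yy)))
  go_left <- X[idx, best$feat] <= best$threshold
  list(leaf = FALSE, feat = best$feat, threshold = best$threshold,
       left = rf_build(X, y, idx[go_left], mtry, min_node, depth + 1L,
                       max_depth),
       right = rf_build(X, y, idx[!go_left], mtry, min_node, depth + 1L,
                        max_depth))
}

rf_predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(nd, idx) {
    if (!length(idx)) return(invisible())
    if (nd$leaf) {
      out[idx] <<- nd$value
      return(invisible())
    }
    go_left <- X[idx, nd$feat] <= nd$threshold
    recurse(nd$left, idx[go_left])
    recurse(nd$right, idx[!go_left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

#' Fit a random-forest regression
#'
#' Bagged CART regression trees: each tree is grown on a bootstrap sample
#' with `mtry = max(1, floor(mtry_frac * p))` randomly chosen candidate
#' features per split and exhaustive variance-reduction split search.
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param n_trees number of trees.
#' @param mtry_frac fraction of features tried per split.
#' @param min_node minimum observations per child node.
#' @param max_depth maximum tree depth.
#' @param seed integer seed (forest growth is stochastic).
#' @return a `calibration_model` with `algorithm = "RF"`.
#' @export
fit_rf <- function(X, y, n_trees = 200, mtry_frac = 1 / 3, min_node = 5,
                   max_depth = 20, seed = 1L) {
  X <- as_X(X)
  y <- as.numeric(y)
  mtry <- max(1L, min(ncol(X), floor(mtry_frac * ncol(X))))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(nrow(X), replace = TRUE)
      rf_build(X[boot, , drop = FALSE], y[boot], seq_along(boot),
               mtry, min_node, 0L, max_depth)
    })
  })
  structure(list(
    algorithm = "RF",
    wavelengths = colnames(X),
    trees = trees,
    hyperparams = list(n_trees = n_trees, mtry_frac = mtry_frac,
                       min_node = min_node, seed = seed)
  ), class = "calibration_model")
}

#' Fit a calibration model by algorithm tag
#'
#' @param X predictor matrix or [spectra_set()].
#' @param y numeric response.
#' @param algorithm `"PLSR"`, `"SVM_RADIAL"` or `"RF"`.
#' @param hyperparams named list, e.g. from [select_hyperparameters()].
#' @return a `calibration_model`.
#' @export
fit_model <- function(X, y, algorithm = c("PLSR", "SVM_RADIAL", "RF"),
                      hyperparams = list()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    PLSR = {
      nc <- hyperparams$n_components %||% 10L
      m <- fit_plsr(X, y, nc)
      if (!is.null(hyperparams$rank)) m$rank <- min(hyperparams$rank, m$rank)
      m
    },
    SVM_RADIAL = do.call(fit_svm_radial,
                         c(list(X = X, y = y),
                           hyperparams[intersect(names(hyperparams),
                                                 c("cost", "gamma"))])),
    RF = do.call(fit_rf,
                 c(list(X = X, y = y),
                   hyperparams[intersect(names(hyperparams),
                                         c("n_trees", "mtry_frac",
                                           "min_node", "max_depth",
                                           "seed"))]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_grid_match <- function(model, X) {
  ok <- if (!is.null(model$wavelengths) && !is.null(colnames(X))) {
    identical(colnames(X), model$wavelengths)
  } else if (!is.null(model$wavelengths)) {
    ncol(X) == length(model$wavelengths)
  } else {
    TRUE
  }
  if (!ok) stop("wavelength grid mismatch between model and new spectra",
                call. = FALSE)
  invisible(TRUE)
}

#' Predict starch from a fitted calibration model
#'
#' @param object a `calibration_model`.
#' @param newdata predictor matrix or [spectra_set()] on the training grid.
#' @param rank PLSR rank to use (default: the model's selected rank).
#' @param ... ignored.
#' @return numeric predictions.
#' @export
predict.calibration_model <- function(object, newdata, rank = NULL, ...) {
  X <- as_X(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  check_grid_match(object, X)
  switch(object$algorithm,
    PLSR = {
      r <- rank %||% object$rank
      if (r < 0L || r > ncol(object$coefficients)) {
        stop("rank out of range", call. = FALSE)
      }
      if (r == 0L) return(rep(object$y_center, nrow(X)))
      as.numeric(sweep(X, 2, object$x_center) %*%
                   object$coefficients[, r] + object$y_center)
    },
    SVM_RADIAL = {
      Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
      K <- rbf_kernel(Xs, object$X_train, object$hyperparams$gamma)
      as.numeric(K %*% object$alpha + object$b)
    },
    RF = {
      preds <- vapply(object$trees, function(tr) rf_predict_tree(tr, X),
                      numeric(nrow(X)))
      if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
    }
  )
}

#' Build deterministic k-fold assignments
#'
#' When `groups` is supplied, whole groups (e.g. genotypes) are assigned to
#' folds so replicate plots never straddle a fold boundary.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param groups optional grouping labels of length `n`.
#' @param seed integer seed.
#' @return integer fold id per row.
#' @export
make_folds <- function(n, k, groups = NULL, seed = 1L) {
  with_seed(seed, {
    if (is.null(groups)) {
      sample(rep_len(seq_len(k), n))
    } else {
      g <- unique(groups)
      gf <- sample(rep_len(seq_len(k), length(g)))
      gf[match(groups, g)]
    }
  })
}

#' Select hyperparameters by k-fold cross-validation
#'
#' Grids: PLSR over rank 1..`max_rank`; SVM over `cost_grid` x
#' `gamma_mult` (multiples of the heuristic default gamma); RF over
#' `rf_grid`. The winner minimises RMSECV; its RMSECV and R2cv (squared
#' Pearson correlation of out-of-fold predictions with `y`) are reported.
#'
#' @param X predictor matrix or [spectra_set()].
#' @param y numeric response.
#' @param algorithm `"PLSR"`, `"SVM_RADIAL"` or `"RF"`.
#' @param k folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param groups optional genotype labels for grouped folds.
#' @param max_rank PLSR rank cap (default 10).
#' @param cost_grid,gamma_mult SVM grids.
#' @param rf_grid data.frame grid with `n_trees` and `mtry_frac`.
#' @return list with `algorithm`, `hyperparams`, `rmsecv`, `r2cv` and the
#'   full `profile` of the search.
#' @export
select_hyperparameters <- function(X, y,
                                   algorithm = c("PLSR", "SVM_RADIAL",
                                                 "RF"),
                                   k = 5L, seed = 1L, groups = NULL,
                                   max_rank = 10L,
                                   cost_grid = c(1, 10, 100),
                                   gamma_mult = c(0.25, 1, 4),
                                   rf_grid = expand.grid(
                                     n_trees = 100,
                                     mtry_frac = c(0.1, 1 / 3))) {
  algorithm <- match.arg(algorithm)
  X <- as_X(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (n < 2L * k) stop("need at least 2 samples per fold", call. = FALSE)
  folds <- make_folds(n, k, groups, seed)
  cv_of <- function(fit_fun, pred_fun) {
    pred <- rep(NA_real_, n)
    for (f in sort(unique(folds))) {
      te <- folds == f
      m <- fit_fun(X[!te, , drop = FALSE], y[!te])
      pred[te] <- pred_fun(m, X[te, , drop = FALSE])
    }
    pred
  }
  if (algorithm == "PLSR") {
    max_rank <- as.integer(max_rank)
    cvp <- matrix(NA_real_, n, max_rank)
    for (f in sort(unique(folds))) {
      te <- folds == f
      m <- fit_plsr(X[!te, , drop = FALSE], y[!te], max_rank)
      for (a in seq_len(ncol(m$coefficients))) {
        cvp[te, a] <- predict(m, X[te, , drop = FALSE], rank = a)
      }
    }
    ok <- colSums(is.na(cvp)) == 0L
    rmse <- sqrt(colMeans((cvp - y)^2))
    rmse[!ok] <- Inf
    best <- which.min(rmse)
    list(algorithm = algorithm,
         hyperparams = list(n_components = max_rank, rank = best),
         rmsecv = rmse[best],
         r2cv = stats::cor(cvp[, best], y)^2,
         profile = data.frame(rank = seq_len(max_rank), rmsecv = rmse))
  } else if (algorithm == "SVM_RADIAL") {
    p <- ncol(X)
    scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, colMeans(X)), 2, scl, `/`)
    gamma0 <- 1 / (p * max(mean(apply(Xs, 2, stats::var)), 1e-12))
    grid <- expand.grid(cost = cost_grid, gamma = gamma0 * gamma_mult)
    grid$rmsecv <- NA_real_
    best <- NULL
    for (i in seq_len(nrow(grid))) {
      pred <- cv_of(
        function(Xtr, ytr) fit_svm_radial(Xtr, ytr, cost = grid$cost[i],
                                          gamma = grid$gamma[i]),
        function(m, Xte) predict(m, Xte))
      grid$rmsecv[i] <- sqrt(mean((pred - y)^2))
      if (is.null(best) || grid$rmsecv[i] < best$rmsecv) {
        best <- list(i = i, rmsecv = grid$rmsecv[i], pred = pred)
      }
    }
    list(algorithm = algorithm,
         hyperparams = list(cost = grid$cost[best$i],
                            gamma = grid$gamma[best$i]),
         rmsecv = best$rmsecv,
         r2cv = stats::cor(best$pred, y)^2,
         profile = grid)
  } else {
    grid <- rf_grid
    grid$rmsecv <- NA_real_
    best <- NULL
    for (i in seq_len(nrow(grid))) {
      pred <- cv_of(
        function(Xtr, ytr) fit_rf(Xtr, ytr, n_trees = grid$n_trees[i],
                                  mtry_frac = grid$mtry_frac[i],
                                  seed = seed + i),
        function(m, Xte) predict(m, Xte))
      grid$rmsecv[i] <- sqrt(mean((pred - y)^2))
      if (is.null(best) || grid$rmsecv[i] < best$rmsecv) {
        best <- list(i = i, rmsecv = grid$rmsecv[i], pred = pred)
      }
    }
    list(algorithm = algorithm,
         hyperparams = list(n_trees = grid$n_trees[best$i],
                            mtry_frac = grid$mtry_frac[best$i],
                            seed = seed),
         rmsecv = best$rmsecv,
         r2cv = stats::cor(best$pred, y)^2,
         profile = grid)
  }
}
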