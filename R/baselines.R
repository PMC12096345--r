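# One-vs-rest baselines over flattened fingerprints: logistic regression
# (ridge, via glmnet), random forest and a kernel support-vector machine in
# its regularized least-squares form. No tree or SVM library exists in the
# target environment, so both are implemented here. The hyperparameter
# search covers regularization strengths {0, 0.2, ..., 1}, the four kernels
# where applicable, and PCA to {25, 50, 75, 100} components or no PCA.

#' Specify a baseline classifier and its search grid
#'
#' @param algorithm One of `"lr"`, `"rf"`, `"svm"` (logistic regression,
#'   random forest, support vector machine). All are one-vs-rest.
#' @param regularization_strengths Grid of penalty strengths; 0 maps to a
#'   penalty-free fit (for the kernel SVM, to a vanishing ridge of 1e-6 so
#'   the normal equations stay solvable).
#' @param kernels Kernel grid, used by the SVM only.
#' @param pca_components PCA grid; `NA` entries mean "no PCA" and the grid
#'   always includes it.
#' @param folds Cross-validation folds for selection, default 3.
#' @param n_trees Random-forest size, default 100.
#' @return Object of class `hsf_baseline_spec`.
#' @export
baseline_spec <- function(algorithm = c("lr", "rf", "svm"),
                          regularization_strengths = seq(0, 1, by = 0.2),
                          kernels = c("linear", "polynomial",
                                      "radial", "sigmoid"),
                          pca_components = c(25L, 50L, 75L, 100L),
                          folds = 3L, n_trees = 100L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, scheme = "one-vs-rest",
                 regularization_strengths = regularization_strengths,
                 kernels = kernels,
                 pca_components = pca_components,
                 folds = as.integer(folds), n_trees = as.integer(n_trees)),
            class = "hsf_baseline_spec")
}

#' Enumerate the hyperparameter grid of a baseline spec
#'
#' Strengths apply to LR and SVM, kernels to SVM only; every algorithm
#' searches the PCA set plus no-PCA. For the default SVM spec this is
#' 6 strengths x 4 kernels x 5 PCA options = 120 candidates.
#'
#' @param spec An `hsf_baseline_spec`.
#' @return Data frame with columns `strength`, `kernel`, `pca`.
#' @export
candidate_grid <- function(spec) {
  pca <- c(spec$pca_components, NA)
  grid <- switch(spec$algorithm,
    lr  = expand.grid(strength = spec$regularization_strengths,
                      kernel = NA_character_, pca = pca,
                      stringsAsFactors = FALSE),
    rf  = expand.grid(strength = NA_real_, kernel = NA_character_, pca = pca,
                      stringsAsFactors = FALSE),
    svm = expand.grid(strength = spec$regularization_strengths,
                      kernel = spec$kernels, pca = pca,
                      stringsAsFactors = FALSE))
  grid
}

# ---- PCA helper ------------------------------------------------------------

fit_pca <- function(X, rank) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  nv <- max(1L, min(rank, nrow(X) - 1L, ncol(X)))  # rank <= min(n-1, p)
  sv <- svd(Xc, nu = 0, nv = nv)
  list(center = mu, rotation = sv$v)
}

apply_pca <- function(pca, X, k) {
  if (is.null(pca) || is.na(k)) return(X)
  sweep(X, 2L, pca$center) %*% pca$rotation[, seq_len(min(k, ncol(pca$rotation))), drop = FALSE]
}

# ---- logistic regression (one-vs-rest ridge, glmnet) -----------------------

fit_lr <- function(X, y, strength) {
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    yy <- as.numeric(y == cl)
    # muffle glmnet's small-class chatter; genuine errors still propagate
    withCallingHandlers(
      glmnet::glmnet(X, yy, family = "binomial", alpha = 0,
                     lambda = strength, standardize = FALSE),
      warning = function(w) {
        if (grepl("dangerous ground|fewer than", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  names(fits) <- classes
  list(fits = fits, classes = classes)
}

score_lr <- function(model, X) {
  s <- vapply(model$fits, function(f)
    as.numeric(stats::predict(f, X, type = "link")), numeric(nrow(X)))
  matrix(s, nrow = nrow(X), dimnames = list(NULL, model$classes))
}

# ---- random forest ---------------------------------------------------------

# Greedy CART split on the gini impurity; returns NULL when no split helps.
best_split <- function(X, yidx, K, mtry) {
  n <- length(yidx)
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), yidx)] <- 1
  parent_gini <- 1 - sum((colSums(Y) / n)^2)
  for (j in feats) {
    xj <- X[, j]
    ord <- order(xj)
    xs <- xj[ord]
    valid <- which(xs[-n] < xs[-1])
    if (!length(valid)) next
    CL <- apply(Y[ord, , drop = FALSE], 2L, cumsum)
    nl <- seq_len(n)
    gl <- 1 - rowSums(CL^2) / nl^2
    CR <- sweep(-CL, 2L, CL[n, ], "+")
    nr <- n - nl
    gr <- numeric(n)
    gr[-n] <- 1 - rowSums(CR[-n, , drop = FALSE]^2) / nr[-n]^2
    w <- (nl * gl + nr * gr) / n
    i <- valid[which.min(w[valid])]
    if (is.null(best) || w[i] < best$score) {
      best <- list(score = w[i], feature = j,
                   threshold = (xs[i] + xs[i + 1]) / 2)
    }
  }
  if (!is.null(best) && best$score >= parent_gini - 1e-12) return(NULL)
  best
}

grow_tree <- function(X, yidx, K, mtry, min_node = 1L, max_depth = 30L) {
  nodes <- list()
  new_node <- function(nd) { nodes[[length(nodes) + 1L]] <<- nd; length(nodes) }
  build <- function(rows, depth) {
    yy <- yidx[rows]
    counts <- tabulate(yy, K)
    if (length(rows) <= min_node || depth >= max_depth ||
        sum(counts > 0) == 1L)
      return(new_node(list(leaf = TRUE, counts = counts)))
    sp <- best_split(X[rows, , drop = FALSE], yy, K, mtry)
    if (is.null(sp))
      return(new_node(list(leaf = TRUE, counts = counts)))
    left <- rows[X[rows, sp$feature] <= sp$threshold]
    right <- setdiff(rows, left)
    if (!length(left) || !length(right))
      return(new_node(list(leaf = TRUE, counts = counts)))
    l <- build(left, depth + 1L)
    r <- build(right, depth + 1L)
    new_node(list(leaf = FALSE, feature = sp$feature,
                  threshold = sp$threshold, left = l, right = r))
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    nd <- tree$nodes[[tree$root]]
    while (!nd$leaf) {
      nd <- tree$nodes[[if (X[i, nd$feature] <= nd$threshold) nd$left
                        else nd$right]]
    }
    out[i] <- which.max(nd$counts)
  }
  out
}

fit_rf <- function(X, y, n_trees, seed = 1L) {
  classes <- levels(y)
  K <- length(classes)
  yidx <- as.integer(y)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(nrow(X), replace = TRUE)
    grow_tree(X[boot, , drop = FALSE], yidx[boot], K, mtry)
  }))
  list(trees = trees, classes = classes)
}

score_rf <- function(model, X) {
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  for (tr in model$trees) {
    p <- predict_tree(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1
  }
  votes / length(model$trees)
}

# ---- kernel SVM (regularized least-squares / ridge formulation) ------------

kernel_matrix <- function(kernel, X, Y, gamma = 1 / ncol(X)) {
  G <- tcrossprod(X, Y)
  switch(kernel,
    linear = G,
    polynomial = (gamma * G + 1)^3,
    radial = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    },
    sigmoid = tanh(gamma * G),
    stop("unknown kernel: ", kernel))
}

fit_svm <- function(X, y, strength, kernel) {
  classes <- levels(y)
  n <- nrow(X)
  # strength 0 = (numerically) penalty-free: vanishing ridge keeps the
  # kernel normal equations solvable
  lam <- if (strength <= 0) 1e-6 else strength
  K <- kernel_matrix(kernel, X, X) + 1   # +1 absorbs the bias term
  Y <- matrix(-1, n, length(classes))
  for (j in seq_along(classes)) Y[y == classes[j], j] <- 1
  R <- K + diag(lam, n)
  alpha <- tryCatch(solve(R, Y), error = function(e)
    solve(R + diag(1e-8 * mean(diag(K)), n), Y))
  list(alpha = alpha, Xtrain = X, kernel = kernel, classes = classes)
}

score_svm <- function(model, X) {
  K <- kernel_matrix(model$kernel, X, model$Xtrain) + 1
  s <- K %*% model$alpha
  colnames(s) <- model$classes
  s
}

# ---- shared fit/predict dispatch -------------------------------------------

fit_one <- function(algorithm, X, y, strength, kernel, n_trees, seed) {
  switch(algorithm,
    lr  = fit_lr(X, y, strength),
    rf  = fit_rf(X, y, n_trees, seed),
    svm = fit_svm(X, y, strength, kernel))
}

score_one <- function(algorithm, model, X) {
  switch(algorithm, lr = score_lr(model, X), rf = score_rf(model, X),
         svm = score_svm(model, X))
}

#' Fit a baseline with exhaustive hyperparameter search
#'
#' Searches the spec's full grid (strengths x kernels where applicable x
#' PCA options) by seeded k-fold selection on the training set, then refits
#' the best configuration on the full training set. Folds whose training
#' part is missing a class are skipped with a warning.
#'
#' @param spec An `hsf_baseline_spec`.
#' @param train An `hsf_library` or `list(X, y)`.
#' @param seed Integer seed (folds, forest bootstraps).
#' @param verbose Print per-candidate accuracy. Default FALSE.
#' @return Object of class `hsf_baseline` with the refit model, the chosen
#'   hyperparameters (`best`) and the full CV table (`cv`).
#' @export
fit_baseline <- function(spec, train, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "hsf_baseline_spec"))
  if (is_library(train))
    train <- library_features(train)
  X <- as.matrix(train$X); y <- droplevels(as.factor(train$y))
  n <- nrow(X)
  grid <- candidate_grid(spec)
  fold_id <- with_seed(derive_seed(seed, "folds"),
                       sample(rep_len(seq_len(spec$folds), n)))
  max_rank <- min(max(spec$pca_components), n - ceiling(n / spec$folds) - 1L,
                  ncol(X))
  # one PCA per fold (components are nested, so each candidate slices it)
  fold_pca <- lapply(seq_len(spec$folds), function(f) {
    tr <- fold_id != f
    fit_pca(X[tr, , drop = FALSE], max_rank)
  })
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(spec$folds)) {
      tr <- which(fold_id != f); va <- which(fold_id == f)
      ytr <- droplevels(y[tr])
      if (nlevels(ytr) < nlevels(y) || min(table(ytr)) < 2L) {
        warning("fold ", f, " is missing a class (or has a singleton class); skipped")
        next
      }
      Xtr <- apply_pca(fold_pca[[f]], X[tr, , drop = FALSE], grid$pca[g])
      Xva <- apply_pca(fold_pca[[f]], X[va, , drop = FALSE], grid$pca[g])
      m <- fit_one(spec$algorithm, Xtr, ytr, grid$strength[g], grid$kernel[g],
                   spec$n_trees, derive_seed(seed, "cv", g, f))
      pred <- levels(ytr)[max.col(score_one(spec$algorithm, m, Xva),
                                  ties.method = "first")]
      correct <- correct + sum(pred == as.character(y[va]))
      total <- total + length(va)
    }
    acc[g] <- if (total) correct / total else NA_real_
    if (verbose)
      message(sprintf("candidate %d/%d (%s): acc %.3f", g, nrow(grid),
                      paste(grid[g, ], collapse = "/"), acc[g]))
  }
  if (all(is.na(acc))) {
    warning("every fold was degenerate; selecting the first candidate")
    best_g <- 1L
  } else best_g <- which.max(acc)
  pca <- if (!is.na(grid$pca[best_g]))
    fit_pca(X, min(max_rank, grid$pca[best_g])) else NULL
  Xb <- apply_pca(pca, X, grid$pca[best_g])
  final <- fit_one(spec$algorithm, Xb, y, grid$strength[best_g],
                   grid$kernel[best_g], spec$n_trees,
                   derive_seed(seed, "final"))
  structure(list(spec = spec, algorithm = spec$algorithm,
                 best = grid[best_g, ], cv = cbind(grid, accuracy = acc),
                 pca = pca, pca_k = grid$pca[best_g],
                 model = final, classes = levels(y),
                 n_features = ncol(X), seed = as.integer(seed)),
            class = "hsf_baseline")
}

#' @export
print.hsf_baseline <- function(x, ...) {
  cat(sprintf("<hsf_baseline> %s (OvR), best: strength=%s kernel=%s pca=%s\n",
              x$algorithm, x$best$strength, x$best$kernel, x$best$pca))
  invisible(x)
}

#' Predict class probabilities from a fitted baseline
#'
#' One-vs-rest decision scores are softmax-normalized into a common
#' probability interface across all four model families.
#'
#' @param object An `hsf_baseline`.
#' @param newdata An `hsf_matrix`, `hsf_library` or feature matrix.
#' @param ... Unused.
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
predict.hsf_baseline <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$n_features)
  X <- apply_pca(object$pca, X, object$pca_k)
  s <- score_one(object$algorithm, object$model, X)
  p <- softmax_rows(as.matrix(s))
  colnames(p) <- object$classes
  p
}
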