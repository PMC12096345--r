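# CNN and one-vs-rest baselines: architecture contracts, gradient
# correctness, training on separable toys, grid enumeration, prediction
# interface and the metric computations.

test_that("toy libraries are separable (nearest-centroid oracle)", {
  lib <- toy_library(n_classes = 3, per_class = 8, seed = 4)
  expect_equal(nearest_centroid_acc(lib), 1)
})

test_that("build_cnn fixes the 3-stage topology and output width", {
  spec <- build_cnn(86)
  expect_length(spec$conv_stages, 3L)
  expect_equal(spec$n_classes, 86L)
  expect_true(all(vapply(spec$conv_stages, `[[`, "", "activation") == "relu"))
  expect_true(all(vapply(spec$conv_stages, `[[`, "", "pooling") == "max"))
  expect_error(build_cnn(1), ">= 2")
  expect_error(build_cnn(3, filters = c(8, 16)), "3 convolution stages")
})

test_that("CNN analytic gradients match finite differences", {
  spec <- build_cnn(3, filters = c(2, 3, 4), dense_width = 6)
  geo <- hsfkit:::cnn_geometry(spec)
  par <- hsfkit:::cnn_init(spec, 3, 42)
  set.seed(11)
  X <- matrix(runif(3 * 4356), 3)
  yidx <- c(1L, 2L, 3L)
  fw <- hsfkit:::cnn_forward(par, X, geo, keep = TRUE)
  gr <- hsfkit:::cnn_backward(par, fw, yidx, geo)
  lossf <- function(p)
    hsfkit:::cnn_loss(hsfkit:::cnn_forward(p, X, geo)$logits, yidx)
  eps <- 1e-5
  for (nm in names(par)) {
    idx <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
    for (i in idx) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- par; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossf(p2) - lossf(p3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("train_cnn reaches 100% training accuracy on a separable toy", {
  lib <- toy_library(n_classes = 3, per_class = 10, seed = 5)
  spec <- build_cnn(3, epochs = 30, batch_size = 8)
  m <- train_cnn(spec, lib, seed = 3)
  r <- evaluate(m, lib)
  expect_equal(r$accuracy, 100)
  # smoothed loss trace is non-increasing
  sm <- stats::filter(m$loss_trace, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05))
  expect_lt(sm[length(sm)], sm[1])
})

test_that("train_cnn is deterministic for a fixed seed", {
  lib <- toy_library(n_classes = 2, per_class = 4, seed = 6)
  spec <- build_cnn(2, filters = c(4, 8, 8), dense_width = 16, epochs = 3)
  m1 <- train_cnn(spec, lib, seed = 9)
  m2 <- train_cnn(spec, lib, seed = 9)
  expect_identical(lapply(m1$par, sum), lapply(m2$par, sum))
  expect_identical(m1$loss_trace, m2$loss_trace)
  m3 <- train_cnn(spec, lib, seed = 10)
  expect_false(identical(m1$par$W5, m3$par$W5))
})

test_that("train_cnn handles a single-class degenerate set", {
  lib <- toy_library(n_classes = 1, per_class = 5, seed = 7)
  spec <- build_cnn(2, filters = c(2, 4, 4), dense_width = 8, epochs = 3)
  m <- train_cnn(spec, lib, seed = 1)
  p <- predict(m, lib)
  expect_equal(colnames(p), "toy_1")
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(evaluate(m, lib)$accuracy, 100)
})

test_that("CNN predictions are probability vectors for any input", {
  lib <- toy_library(n_classes = 3, per_class = 4, seed = 8)
  spec <- build_cnn(3, filters = c(2, 4, 4), dense_width = 8, epochs = 2)
  m <- train_cnn(spec, lib, seed = 2)
  p <- predict(m, lib)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, length(lib)), tolerance = 1e-6)
  # all-zero fingerprint: still a valid distribution
  p0 <- predict(m, matrix(0, 1, 4356))
  expect_equal(sum(p0), 1, tolerance = 1e-6)
  expect_true(all(p0 >= 0))
  # shape mismatch
  expect_error(predict(m, matrix(0, 1, 100)), "does not match")
})

test_that("candidate grids enumerate exactly the stated search space", {
  expect_equal(nrow(candidate_grid(baseline_spec("svm"))), 120L) # 6*4*5
  expect_equal(nrow(candidate_grid(baseline_spec("lr"))), 30L)   # 6*5
  expect_equal(nrow(candidate_grid(baseline_spec("rf"))), 5L)    # 5 PCA opts
  g <- candidate_grid(baseline_spec("svm"))
  expect_setequal(unique(g$strength), seq(0, 1, by = 0.2))
  expect_setequal(unique(g$kernel), c("linear", "polynomial", "radial",
                                      "sigmoid"))
  expect_setequal(unique(g$pca), c(25L, 50L, 75L, 100L, NA))
})

test_that("all three baselines reach 100% on a separable toy", {
  lib <- toy_library(n_classes = 3, per_class = 12, seed = 10)
  sp <- shuffle_split(lib, 0.75, seed = 1)
  tr <- lib[sp$train]; te <- lib[sp$test]
  small <- function(alg) baseline_spec(
    alg, regularization_strengths = c(0, 0.4),
    kernels = c("linear", "radial"), pca_components = c(10L),
    folds = 3L, n_trees = 25L)
  for (alg in c("lr", "rf", "svm")) {
    m <- fit_baseline(small(alg), tr, seed = 4)
    r <- evaluate(m, te)
    expect_equal(r$accuracy, 100, info = alg)
    p <- predict(m, te)
    expect_equal(rowSums(p), rep(1, length(te)), tolerance = 1e-6)
  }
})

test_that("strength 0.0 maps to a penalty-free fit", {
  lib <- toy_library(n_classes = 2, per_class = 8, seed = 12)
  f <- hsfkit:::library_features(lib)
  Xp <- hsfkit:::apply_pca(hsfkit:::fit_pca(f$X, 5), f$X, 5)
  m_lr <- hsfkit:::fit_lr(Xp, f$y, strength = 0)
  expect_equal(m_lr$fits[[1]]$lambda, 0)
  s <- hsfkit:::score_lr(m_lr, Xp)
  expect_equal(levels(f$y)[max.col(s)], as.character(f$y))
  m_svm <- hsfkit:::fit_svm(Xp, f$y, strength = 0, kernel = "linear")
  expect_equal(levels(f$y)[max.col(hsfkit:::score_svm(m_svm, Xp))],
               as.character(f$y))
})

test_that("fit_baseline skips degenerate folds with a warning", {
  lib <- toy_library(n_classes = 3, per_class = 2, seed = 13)
  spec <- baseline_spec("lr", regularization_strengths = 0.4,
                        pca_components = integer(0), folds = 3L)
  expect_warning(fit_baseline(spec, lib, seed = 2), "missing a class")
})

test_that("evaluate matches a brute-force metrics oracle", {
  # all-correct predictions
  r <- hsfkit:::metrics_from_predictions(rep(c("a", "b"), 5),
                                         rep(c("a", "b"), 5))
  expect_equal(r$accuracy, 100)
  expect_equal(r$macro_f1, 100)

  # 344 test examples with 3 errors -> 99.1% to one decimal place
  truth <- rep("a", 344)
  pred <- c(rep("b", 3), rep("a", 341))
  r <- hsfkit:::metrics_from_predictions(truth, pred, c("a", "b"))
  expect_equal(round(r$accuracy, 1), 99.1)

  # hand-computed 2-class confusion [[8,2],[1,9]]
  conf <- matrix(c(8, 1, 2, 9), 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- metrics_from_confusion(conf)
  prec_a <- 8 / 9; prec_b <- 9 / 11
  rec_a <- 8 / 10; rec_b <- 9 / 10
  expect_equal(r$accuracy, 100 * 17 / 20)
  expect_equal(r$macro_precision, 100 * mean(c(prec_a, prec_b)))
  expect_equal(r$macro_recall, 100 * mean(c(rec_a, rec_b)))
  f1a <- 2 * prec_a * rec_a / (prec_a + rec_a)
  f1b <- 2 * prec_b * rec_b / (prec_b + rec_b)
  expect_equal(r$macro_f1, 100 * mean(c(f1a, f1b)))
  expect_equal(sum(r$confusion), r$n_test)
  expect_equal(r$misclassifications$count, c(2, 1))

  # randomized cross-check against an independent per-class loop
  set.seed(20)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    truth <- sample(letters[1:k], 60, replace = TRUE)
    pred <- ifelse(stats::runif(60) < 0.7, truth,
                   sample(letters[1:k], 60, replace = TRUE))
    r <- hsfkit:::metrics_from_predictions(truth, pred, letters[1:k])
    present <- sort(unique(truth))
    oracle <- sapply(present, function(cl) {
      tp <- sum(truth == cl & pred == cl)
      c(p = if (sum(pred == cl)) tp / sum(pred == cl) else 0,
        r = tp / sum(truth == cl))
    })
    expect_equal(r$accuracy, 100 * mean(truth == pred))
    expect_equal(r$macro_precision, 100 * mean(oracle["p", ]))
    expect_equal(r$macro_recall, 100 * mean(oracle["r", ]))
  }
})

test_that("evaluate rejects unknown test classes", {
  lib <- toy_library(n_classes = 2, per_class = 4, seed = 14)
  spec <- build_cnn(2, filters = c(2, 2, 2), dense_width = 4, epochs = 1)
  m <- train_cnn(spec, lib, seed = 1)
  bad <- lib
  bad[[1]]$class_id <- "mystery"
  expect_error(evaluate(m, bad), "unknown")
})

test_that("confusion-matrix marginals conserve test counts", {
  lib <- toy_library(n_classes = 3, per_class = 6, seed = 15)
  spec <- build_cnn(3, filters = c(2, 4, 4), dense_width = 8, epochs = 5)
  m <- train_cnn(spec, lib, seed = 5)
  r <- evaluate(m, lib)
  expect_equal(unname(rowSums(r$confusion)[paste0("toy_", 1:3)]),
               rep(6, 3), ignore_attr = TRUE)
  expect_equal(sum(r$confusion), 18)
})
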