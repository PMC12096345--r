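# Small convolutional network over 66 x 66 x 1 fingerprints, implemented
# directly on BLAS matrix products (im2col convolution, non-overlapping
# 2 x 2 max pooling, one hidden dense layer, softmax output, Adam).
# No deep-learning runtime is available in the target environment, so the
# forward/backward passes live here; they are exercised against
# finite-difference gradients in the test suite.

#' Specify the CNN architecture
#'
#' Three convolution stages (3 x 3 kernels, rectified-linear activation,
#' 2 x 2 max pooling each), a flatten, one rectified-linear dense layer and
#' a softmax output of width `n_classes`. Filter counts, dense width and
#' the optimizer settings are tunable; the three-stage topology is fixed.
#'
#' @param n_classes Number of output classes, >= 2.
#' @param filters Integer vector of length 3: filters per conv stage.
#' @param dense_width Width of the hidden dense layer.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param input_dim Side of the square input, default 66.
#' @return Object of class `hsf_cnn_spec`.
#' @export
build_cnn <- function(n_classes, filters = c(16L, 32L, 64L),
                      dense_width = 128L, learning_rate = 3e-3,
                      epochs = 30L, batch_size = 32L, input_dim = 66L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(filters) != 3L) stop("exactly 3 convolution stages")
  structure(list(
    input_shape = c(input_dim, input_dim, 1L),
    conv_stages = lapply(1:3, function(i)
      list(filters = as.integer(filters[i]), kernel = 3L,
           activation = "relu", pooling = "max", pool = 2L)),
    dense_widths = as.integer(dense_width),
    n_classes = as.integer(n_classes),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size)),
    class = "hsf_cnn_spec")
}

# Geometry of one conv(+pool) stage: valid 3x3 conv then 2x2/2 max pool.
conv_geometry <- function(in_dim, in_ch, k = 3L, pool = 2L) {
  out_dim <- in_dim - k + 1L
  pool_dim <- out_dim %/% pool
  # im2col index matrix: rows = output positions (row-major in (i,j) with i
  # fastest, i.e. column-major grid), cols = (di, dj, c) offsets
  pos_i <- rep(seq_len(out_dim), times = out_dim)
  pos_j <- rep(seq_len(out_dim), each = out_dim)
  idx <- matrix(0L, nrow = out_dim^2, ncol = k * k * in_ch)
  col <- 0L
  for (c in seq_len(in_ch)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    col <- col + 1L
    idx[, col] <- (pos_i + di) + (pos_j + dj - 1L) * in_dim +
      (c - 1L) * in_dim * in_dim
  }
  # pooling source positions: 4 disjoint index vectors into the out_dim grid
  pi <- rep(seq_len(pool_dim), times = pool_dim)
  pj <- rep(seq_len(pool_dim), each = pool_dim)
  base_i <- (pi - 1L) * pool + 1L
  base_j <- (pj - 1L) * pool + 1L
  pool_idx <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                     function(d) (base_i + d[1]) + (base_j + d[2] - 1L) * out_dim)
  list(in_dim = in_dim, in_ch = in_ch, out_dim = out_dim,
       pool_dim = pool_dim, idx = idx, pool_idx = pool_idx,
       in_len = in_dim * in_dim * in_ch)
}

# Expand single-image indices to a batch of B stacked images.
batch_idx <- function(idx_vec_or_mat, n_per_img, img_len, B) {
  if (is.matrix(idx_vec_or_mat)) {
    rows <- idx_vec_or_mat[rep(seq_len(nrow(idx_vec_or_mat)), times = B), ,
                           drop = FALSE]
    rows + rep((seq_len(B) - 1L) * img_len, each = nrow(idx_vec_or_mat))
  } else {
    rep(idx_vec_or_mat, times = B) +
      rep((seq_len(B) - 1L) * img_len, each = length(idx_vec_or_mat))
  }
}

cnn_geometry <- function(spec) {
  g1 <- conv_geometry(spec$input_shape[1], 1L)
  g2 <- conv_geometry(g1$pool_dim, spec$conv_stages[[1]]$filters)
  g3 <- conv_geometry(g2$pool_dim, spec$conv_stages[[2]]$filters)
  flat <- g3$pool_dim^2 * spec$conv_stages[[3]]$filters
  list(stages = list(g1, g2, g3), flat = flat)
}

cnn_init <- function(spec, n_out, seed) {
  geo <- cnn_geometry(spec)
  f <- vapply(spec$conv_stages, `[[`, 1L, "filters")
  with_seed(seed, {
    he <- function(fan_in, nr, nc)
      matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    list(W1 = he(9, 9, f[1]), b1 = numeric(f[1]),
         W2 = he(9 * f[1], 9 * f[1], f[2]), b2 = numeric(f[2]),
         W3 = he(9 * f[2], 9 * f[2], f[3]), b3 = numeric(f[3]),
         W4 = he(geo$flat, geo$flat, spec$dense_widths[1]),
         b4 = numeric(spec$dense_widths[1]),
         W5 = he(spec$dense_widths[1], spec$dense_widths[1], n_out),
         b5 = numeric(n_out))
  })
}

# Forward pass over a batch. X: B x 4356 (column-major flattened images).
# Returns logits and, when keep = TRUE, the caches needed for backward.
cnn_forward <- function(par, X, geo, keep = FALSE) {
  B <- nrow(X)
  caches <- vector("list", 3L)
  ximg <- t(X)                       # in_len x B
  for (s in 1:3) {
    g <- geo$stages[[s]]
    W <- par[[paste0("W", s)]]; b <- par[[paste0("b", s)]]
    bidx <- batch_idx(g$idx, g$out_dim^2, g$in_len, B)
    xcol <- matrix(ximg[bidx], nrow = g$out_dim^2 * B)
    z <- sweep(xcol %*% W, 2L, b, "+")
    a <- z * (z > 0)
    # max pool over 4 disjoint source sets
    pool_rows <- lapply(g$pool_idx, function(pv)
      batch_idx(pv, length(pv), g$out_dim^2, B))
    cand <- lapply(pool_rows, function(rw) a[rw, , drop = FALSE])
    m <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
    if (keep) {
      masks <- vector("list", 4L)
      taken <- matrix(FALSE, nrow(m), ncol(m))
      for (q in 1:4) {
        mq <- (cand[[q]] == m) & !taken
        taken <- taken | mq
        masks[[q]] <- mq
      }
      caches[[s]] <- list(xcol = xcol, bidx = bidx, z = z,
                          pool_rows = pool_rows, masks = masks,
                          a_dim = c(g$out_dim^2 * B, ncol(a)))
    }
    # reorder pooled maps (B*poolHW x F) into next layer's image layout
    HW <- g$pool_dim^2; f <- ncol(m)
    arr <- array(m, c(HW, B, f))
    ximg <- matrix(aperm(arr, c(1, 3, 2)), nrow = HW * f)
  }
  xflat <- t(ximg)                   # B x flat
  z4 <- sweep(xflat %*% par$W4, 2L, par$b4, "+")
  h4 <- z4 * (z4 > 0)
  logits <- sweep(h4 %*% par$W5, 2L, par$b5, "+")
  if (keep)
    list(logits = logits, xflat = xflat, z4 = z4, h4 = h4, caches = caches,
         B = B)
  else list(logits = logits)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward pass; yidx = integer class index per row. Returns gradient list.
cnn_backward <- function(par, fw, yidx, geo) {
  B <- fw$B
  p <- softmax_rows(fw$logits)
  dlog <- p
  dlog[cbind(seq_len(B), yidx)] <- dlog[cbind(seq_len(B), yidx)] - 1
  dlog <- dlog / B
  g <- list()
  g$W5 <- crossprod(fw$h4, dlog); g$b5 <- colSums(dlog)
  dh4 <- tcrossprod(dlog, par$W5) * (fw$z4 > 0)
  g$W4 <- crossprod(fw$xflat, dh4); g$b4 <- colSums(dh4)
  dximg <- t(tcrossprod(dh4, par$W4))   # flat-layout (HW*f x B)
  for (s in 3:1) {
    gg <- geo$stages[[s]]
    ca <- fw$caches[[s]]
    HW <- gg$pool_dim^2; f <- ncol(ca$z)
    # invert the image-layout reordering: dximg (HW*f x B) -> dM (B*HW x f)
    arr <- aperm(array(dximg, c(HW, f, B)), c(1, 3, 2))
    dM <- matrix(arr, nrow = HW * B)
    # unpool through the argmax masks, then through ReLU
    da <- matrix(0, ca$a_dim[1], ca$a_dim[2])
    for (q in 1:4)
      da[ca$pool_rows[[q]], ] <- dM * ca$masks[[q]]
    dz <- da * (ca$z > 0)
    g[[paste0("W", s)]] <- crossprod(ca$xcol, dz)
    g[[paste0("b", s)]] <- colSums(dz)
    if (s > 1L) {
      dxcol <- tcrossprod(dz, par[[paste0("W", s)]])
      dvec <- numeric(gg$in_len * B)
      for (k in seq_len(ncol(ca$bidx)))  # offsets are disjoint per column
        dvec[ca$bidx[, k]] <- dvec[ca$bidx[, k]] + dxcol[, k]
      dximg <- matrix(dvec, nrow = gg$in_len)
    }
  }
  g
}

cnn_loss <- function(logits, yidx) {
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_along(yidx), yidx)], 1e-12)))
}

#' Train the CNN
#'
#' Minibatch Adam on softmax cross-entropy. Fully deterministic for a given
#' seed (weight initialization and epoch shuffles use a private RNG
#' stream).
#'
#' @param spec An `hsf_cnn_spec` from [build_cnn()].
#' @param train An `hsf_library` of labelled examples, or a
#'   `list(X, y)` with `X` a numeric matrix (rows = flattened 66 x 66
#'   fingerprints) and `y` a factor.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss. Default FALSE.
#' @return Object of class `hsf_cnn`: trained parameters, class levels and
#'   the per-epoch training-loss trace.
#' @export
train_cnn <- function(spec, train, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "hsf_cnn_spec"))
  if (is_library(train))
    train <- library_features(train)
  X <- train$X; y <- droplevels(as.factor(train$y))
  if (nrow(X) == 0L) stop("empty training set")
  if (ncol(X) != prod(spec$input_shape))
    stop("fingerprint length ", ncol(X), " does not match input shape")
  classes <- levels(y)
  n_out <- max(2L, length(classes))   # width-1 softmax is degenerate
  yidx <- as.integer(y)
  # centre each input cell on its training mean: removes the large structure
  # shared by every fingerprint (LED lines, padding) so that optimization
  # spends its steps on the class differences
  center <- colMeans(X)
  X <- sweep(X, 2L, center)
  geo <- cnn_geometry(spec)
  par <- cnn_init(spec, n_out, derive_seed(seed, "init"))
  mom <- lapply(par, function(w) w * 0)
  vel <- lapply(par, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- numeric(spec$epochs)
  n <- nrow(X)
  for (ep in seq_len(spec$epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep), sample.int(n))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = spec$batch_size)) {
      take <- ord[start:min(start + spec$batch_size - 1L, n)]
      fw <- cnn_forward(par, X[take, , drop = FALSE], geo, keep = TRUE)
      ep_loss <- ep_loss + cnn_loss(fw$logits, yidx[take]); nb <- nb + 1L
      gr <- cnn_backward(par, fw, yidx[take], geo)
      step <- step + 1L
      for (nm in names(par)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    trace[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, spec$epochs,
                                 trace[ep]))
  }
  structure(list(spec = spec, par = par, classes = classes,
                 center = center, loss_trace = trace,
                 seed = as.integer(seed)),
            class = "hsf_cnn")
}

#' @export
print.hsf_cnn <- function(x, ...) {
  cat(sprintf("<hsf_cnn> %d classes, %d epochs, final loss %.4f\n",
              length(x$classes), length(x$loss_trace),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict class probabilities from a trained CNN
#'
#' @param object An `hsf_cnn`.
#' @param newdata An `hsf_matrix`, an `hsf_library`, or a numeric matrix of
#'   flattened fingerprints (rows = examples).
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict.hsf_cnn <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, prod(object$spec$input_shape))
  X <- sweep(X, 2L, object$center)
  geo <- cnn_geometry(object$spec)
  p <- softmax_rows(cnn_forward(object$par, X, geo)$logits)
  k <- length(object$classes)
  if (ncol(p) > k) {                 # drop dead padding column (1-class fit)
    p <- p[, seq_len(k), drop = FALSE]
    p <- p / pmax(rowSums(p), 1e-12)
  }
  colnames(p) <- object$classes
  p
}

# Shared input coercion for all predictors.
as_feature_matrix <- function(newdata, want_len) {
  X <- if (inherits(newdata, "hsf_matrix"))
    matrix(as.vector(newdata$values), nrow = 1L)
  else if (is_library(newdata))
    library_features(newdata)$X
  else as.matrix(newdata)
  if (ncol(X) != want_len)
    stop("fingerprint length ", ncol(X), " does not match model input ",
         want_len)
  X
}
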