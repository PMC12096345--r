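# Shared fixtures: noiseless device variants, registry subsets, and toy
# separable fingerprint libraries for the model tests.

quiet_device <- function(...) {
  device_config(noise_floor = 0, shot_noise_scale = 0, ...)
}

registry_subset <- function(idx) {
  structure(default_registry()[idx], class = "hsf_registry")
}

# Registry entries reduced to tiny counts for fast end-to-end tests.
tiny_registry <- function(idx, count = 3L) {
  reg <- default_registry()[idx]
  for (i in seq_along(reg)) reg[[i]]$raw_example_count <- count
  structure(reg, class = "hsf_registry")
}

# Render a Gaussian blob at a class-specific position into a 66 x 66 x 1
# fingerprint; classes are separable by construction (verified by the
# nearest-centroid oracle test).
toy_fingerprint <- function(class_k, jitter_seed) {
  g <- expand.grid(r = 1:66, c = 1:66)
  cx <- 12 + 14 * ((class_k - 1) %% 4)
  cy <- 12 + 14 * ((class_k - 1) %/% 4)
  set.seed(jitter_seed)
  v <- exp(-((g$r - cx)^2 + (g$c - cy)^2) / (2 * 6^2)) +
    rnorm(4356, 0, 0.02)
  v <- pmin(pmax(v, 0), 1)
  arr <- array(v, dim = c(66L, 66L, 1L))
  structure(list(values = arr, pad_count = 0L, n_bins = 363L,
                 provenance = sprintf("toy_%d_%d", class_k, jitter_seed)),
            class = "hsf_matrix")
}

toy_library <- function(n_classes = 3L, per_class = 10L, seed = 1L) {
  out <- list()
  for (k in seq_len(n_classes))
    for (r in seq_len(per_class))
      out[[length(out) + 1L]] <- list(
        fingerprint = toy_fingerprint(k, seed * 1000L + k * 100L + r),
        class_id = paste0("toy_", k),
        seed = seed)
  structure(out, class = "hsf_library")
}

# Independent nearest-centroid classifier used as a separability oracle.
nearest_centroid_acc <- function(lib) {
  f <- hsfkit:::library_features(lib)
  cls <- levels(f$y)
  cent <- t(vapply(cls, function(cl) colMeans(f$X[f$y == cl, , drop = FALSE]),
                   numeric(ncol(f$X))))
  d2 <- outer(rowSums(f$X^2), rowSums(cent^2), "+") - 2 * f$X %*% t(cent)
  mean(cls[max.col(-d2)] == as.character(f$y))
}
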