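# The labelled synthetic library: an 86-class registry of
# drug / variant / concentration-band conditions, scan simulation for each
# raw example, oversampling with replacement to 20 per class, and the
# seeded shuffled 80/20 split.

registry_entry <- function(class_id, drug, variant, band, components, count) {
  list(class_id = class_id, drug = drug, variant = variant,
       concentration_band = band, components = components,
       raw_example_count = as.integer(count))
}

# Concentration triples (mg/mL) for the benzodiazepine low/medium/high bands.
# Alprazolam, etizolam and lorazepam use the tablet-derived values
# (0.25/0.5/1.5 mg, 0.75/1.5/3 mg and 0.5/2/4 mg in 2.5 mL respectively);
# the remaining triples are plausible dose-relative choices.
bzd_bands <- function() {
  list(alprazolam    = c(0.1, 0.2, 0.6),
       etizolam      = c(0.3, 0.6, 1.2),
       lorazepam     = c(0.2, 0.8, 1.6),
       diazepam      = c(0.5, 1.0, 2.0),
       clobazam      = c(0.4, 1.0, 2.0),
       clonazepam    = c(0.2, 0.8, 1.6),
       nitrazepam    = c(0.25, 1.0, 2.0),
       flubromazolam = c(0.1, 0.25, 0.5),
       flunitrazolam = c(0.1, 0.25, 0.5),
       bromazolam    = c(0.2, 0.5, 1.0),
       phenazepam    = c(0.3, 0.8, 1.5))
}

#' Default 86-class registry
#'
#' The packaged class registry mirrors the structure of the device's
#' training library: 11 benzodiazepines at low/medium/high concentration
#' bands (33 classes), 18 single-drug classes (opioids, nitazenes, party
#' drugs, cutting agents, two distinct seized ketamine lots), 7 two-drug
#' mixtures (nitazene + benzodiazepine, heroin + nitazene,
#' fentanyl + xylazine, diazepam + cutting agents/clobazam), 4 nondrug
#' controls (white paper, blank solvent, lactose, cellulose) and 24
#' deterministic filler compounds, for 86 classes in total. Raw example
#' counts default to 20; the 24 filler classes and the blank have 10 each,
#' so the raw library totals 1470 examples.
#'
#' @return Object of class `hsf_registry`: a list of entries, each with
#'   `class_id`, `drug`, `variant`, `concentration_band`, `components`
#'   (named mg/mL vector) and `raw_example_count`.
#' @export
#' @examples
#' reg <- default_registry()
#' length(reg)                                   # 86
#' sum(vapply(reg, `[[`, 1L, "raw_example_count"))  # 1470
default_registry <- function() {
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  band_names <- c("low", "medium", "high")
  for (drug in names(bzd_bands())) {
    concs <- bzd_bands()[[drug]]
    for (b in 1:3) {
      conc <- concs[b]
      names(conc) <- drug
      add(registry_entry(paste0(drug, "_", band_names[b]), drug, "standard",
                         band_names[b], conc, 20L))
    }
  }

  singles <- list(
    caffeine = c(caffeine = 0.25), paracetamol = c(paracetamol = 20),
    ibuprofen = c(ibuprofen = 20),
    heroin_street = c(heroin = 1, noscapine = 0.3),
    etonitazene = c(etonitazene = 0.5), metonitazene = c(metonitazene = 0.5),
    fentanyl = c(fentanyl = 1), xylazine = c(xylazine = 0.33),
    tramadol = c(tramadol = 20), oxycodone = c(oxycodone = 4),
    buprenorphine = c(buprenorphine = 0.8),
    dihydrocodeine = c(dihydrocodeine = 12),
    cocaine = c(cocaine = 2), ketamine_sample_a = c(ketamine = 2),
    ketamine_sample_b = c(ketamine_b = 2), mdma = c(mdma = 2),
    mephedrone = c(mephedrone = 2), `2cb` = c(`2cb` = 2))
  for (nm in names(singles)) {
    drug <- sub("_(street|sample_[ab])$", "", nm)
    variant <- if (grepl("street", nm)) "street"
      else if (grepl("sample_a", nm)) "sample_a"
      else if (grepl("sample_b", nm)) "sample_b" else "standard"
    add(registry_entry(nm, drug, variant, "n/a", singles[[nm]], 20L))
  }

  mixtures <- list(
    diazepam_caffeine = c(diazepam = 1, caffeine = 0.25),
    diazepam_paracetamol = c(diazepam = 1, paracetamol = 20),
    diazepam_ibuprofen = c(diazepam = 1, ibuprofen = 20),
    diazepam_clobazam = c(diazepam = 1, clobazam = 1),
    heroin_etonitazene = c(heroin = 1, noscapine = 0.3, etonitazene = 0.5),
    bromazolam_metonitazene = c(bromazolam = 0.2, metonitazene = 0.5),
    fentanyl_xylazine = c(fentanyl = 1, xylazine = 0.33))
  for (nm in names(mixtures))
    add(registry_entry(nm, nm, "mixture", "n/a", mixtures[[nm]], 20L))

  add(registry_entry("white_paper", "white_paper", "nondrug", "n/a",
                     c(white_paper = 5), 20L))
  add(registry_entry("lactose", "lactose", "nondrug", "n/a",
                     c(lactose = 20), 20L))
  add(registry_entry("cellulose", "cellulose", "nondrug", "n/a",
                     c(cellulose = 20), 20L))
  add(registry_entry("blank_solvent", "none", "nondrug", "n/a",
                     numeric(0), 10L))

  for (k in 1:24) {
    nm <- sprintf("nps_%02d", k)
    add(registry_entry(nm, nm, "filler", "n/a",
                       stats::setNames(1, nm), 10L))
  }

  ids <- vapply(entries, `[[`, "", "class_id")
  stopifnot(length(entries) == 86L, !anyDuplicated(ids))
  structure(entries, class = "hsf_registry")
}

#' @export
print.hsf_registry <- function(x, ...) {
  cat("<hsf_registry>", length(x), "classes,",
      sum(vapply(x, `[[`, 1L, "raw_example_count")), "raw examples\n")
  invisible(x)
}

#' Write / read a class registry as JSON
#' @param registry An `hsf_registry`.
#' @param path File path.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "hsf_registry"))
  out <- lapply(registry, function(e) {
    e$components <- as.list(e$components)
    e
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(e)
    registry_entry(e$class_id, e$drug, e$variant, e$concentration_band,
                   unlist(e$components) %||% numeric(0),
                   e$raw_example_count))
  structure(entries, class = "hsf_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the labelled fingerprint library
#'
#' For every registry entry, simulates `raw_example_count` device scans of
#' the entry's sample and preprocesses each into a fingerprint. Each
#' example's scan seed is derived deterministically from the master seed,
#' the class id and the replicate index, so the library is byte-identical
#' for a given seed.
#'
#' @param registry An `hsf_registry` (default [default_registry()]).
#' @param config An `hsf_device`.
#' @param seed Integer master seed.
#' @param trim_window,n_bins Preprocessing parameters.
#' @param progress Print per-class progress. Default FALSE.
#' @return List of labelled examples, each
#'   `list(fingerprint, class_id, seed)`, of class `hsf_library`.
#' @export
generate_library <- function(registry = default_registry(),
                             config = device_config(), seed = 17L,
                             trim_window = c(250, 655), n_bins = 360L,
                             progress = FALSE) {
  stopifnot(inherits(registry, "hsf_registry"))
  out <- vector("list", sum(vapply(registry, `[[`, 1L, "raw_example_count")))
  j <- 0L
  for (entry in registry) {
    smp <- do.call(make_sample, as.list(entry$components))
    for (r in seq_len(entry$raw_example_count)) {
      s <- derive_seed(seed, entry$class_id, r)
      scan <- acquire_scan(smp, config, seed = s,
                           sample_id = paste0(entry$class_id, "#", r))
      j <- j + 1L
      out[[j]] <- list(fingerprint = preprocess_scan(scan, trim_window, n_bins),
                       class_id = entry$class_id, seed = s)
    }
    if (progress) message("simulated class ", entry$class_id)
  }
  structure(out, class = "hsf_library")
}

#' Balance a library by oversampling with replacement
#'
#' Classes with fewer than `per_class` examples are oversampled with
#' replacement up to `per_class`; classes already at `per_class` pass
#' through untouched; classes above it are randomly subsampled without
#' replacement down to `per_class` (an extension for non-default
#' registries).
#'
#' @param examples An `hsf_library` (or list of labelled examples).
#' @param per_class Target examples per class, default 20.
#' @param seed Integer seed for the resampling draws.
#' @return Balanced `hsf_library` with exactly
#'   `per_class * n_classes` examples, grouped by class.
#' @export
balance_oversample <- function(examples, per_class = 20L, seed = 17L) {
  labs <- vapply(examples, `[[`, "", "class_id")
  classes <- unique(labs)
  if (any(table(labs) < 1L)) stop("every class needs at least one example")
  out <- list()
  with_seed(derive_seed(seed, "balance"), {
    for (cl in classes) {
      idx <- which(labs == cl)
      # note idx[sample.int(...)]: sample(idx, ...) misbehaves for length-1 idx
      take <- if (length(idx) == per_class) idx
        else if (length(idx) < per_class)
          c(idx, idx[sample.int(length(idx), per_class - length(idx),
                                replace = TRUE)])
        else idx[sample.int(length(idx), per_class, replace = FALSE)]
      out <- c(out, examples[take])
    }
  })
  structure(out, class = "hsf_library")
}

#' Shuffle and split a library into train and test sets
#'
#' Uniform seeded shuffle; the first `floor(train_fraction * N)` examples
#' form the training set, the remainder the test set.
#'
#' @param examples An `hsf_library`.
#' @param train_fraction Fraction for training, default 0.8.
#' @param seed Integer seed.
#' @return Object of class `hsf_split`: list with integer index vectors
#'   `train` and `test` (disjoint, union = all), and `seed`.
#' @export
shuffle_split <- function(examples, train_fraction = 0.8, seed = 17L) {
  n <- length(examples)
  if (n < 2L) stop("need at least 2 examples to split")
  perm <- with_seed(derive_seed(seed, "split"), sample.int(n))
  n_train <- floor(train_fraction * n)
  structure(list(train = perm[seq_len(n_train)],
                 test = perm[seq.int(n_train + 1L, n)],
                 seed = as.integer(seed)),
            class = "hsf_split")
}

is_library <- function(x) {
  inherits(x, "hsf_library") ||
    (is.list(x) && length(x) && is.list(x[[1]]) &&
       !is.null(x[[1]]$fingerprint))
}

# Flatten a library into a feature matrix + factor labels for the models.
library_features <- function(examples) {
  X <- t(vapply(examples, function(e) as.vector(e$fingerprint$values),
                numeric(4356)))
  y <- factor(vapply(examples, `[[`, "", "class_id"))
  list(X = X, y = y)
}
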