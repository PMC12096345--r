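# Packaged compound pool. All optics are synthetic stand-ins: Gaussian band
# parameters chosen so that fingerprint maxima sit at positions reported for
# the real compounds where such anchors exist (bromazolam ex 283 / em ~310 nm,
# diazepam em ~355 nm, caffeine 265/310, paracetamol 285/325, ibuprofen
# 265-285/~290 nm), and are otherwise plausible-but-invented. Quantum yields
# for benzodiazepines are kept low relative to the brighter fluorophores.

compound_table <- function() {
  list(
    # --- benzodiazepines -------------------------------------------------
    alprazolam    = list(abs = list(c(265, 35, 2.2)), em = list(c(365, 55, 1)), qy = 0.15),
    etizolam      = list(abs = list(c(270, 38, 1.8)), em = list(c(380, 60, 1)), qy = 0.12),
    lorazepam     = list(abs = list(c(285, 40, 1.5)), em = list(c(400, 65, 1)), qy = 0.10),
    diazepam      = list(abs = list(c(315, 45, 1.6)), em = list(c(355, 50, 1)), qy = 0.18),
    clobazam      = list(abs = list(c(290, 36, 1.4)), em = list(c(345, 48, 1)), qy = 0.14),
    clonazepam    = list(abs = list(c(310, 42, 2.0)), em = list(c(430, 70, 1)), qy = 0.08),
    nitrazepam    = list(abs = list(c(330, 45, 1.9)), em = list(c(455, 75, 1)), qy = 0.07),
    flubromazolam = list(abs = list(c(275, 34, 2.1)), em = list(c(370, 52, 1)), qy = 0.16),
    flunitrazolam = list(abs = list(c(320, 40, 2.3)), em = list(c(470, 80, 1)), qy = 0.06),
    bromazolam    = list(abs = list(c(283, 33, 2.0)), em = list(c(310, 35, 1)), qy = 0.20),
    phenazepam    = list(abs = list(c(262, 36, 1.7)), em = list(c(390, 60, 1)), qy = 0.11),
    # --- opioids, nitazenes, adulterated street drugs --------------------
    heroin        = list(abs = list(c(279, 30, 1.2)), em = list(c(320, 40, 1)), qy = 0.25),
    noscapine     = list(abs = list(c(292, 34, 1.0)), em = list(c(430, 60, 1)), qy = 0.30),
    etonitazene   = list(abs = list(c(308, 38, 2.4)), em = list(c(395, 55, 1)), qy = 0.22),
    metonitazene  = list(abs = list(c(300, 36, 2.2)), em = list(c(405, 58, 1)), qy = 0.20),
    fentanyl      = list(abs = list(c(258, 26, 0.9)), em = list(c(288, 30, 1)), qy = 0.28),
    xylazine      = list(abs = list(c(268, 30, 1.1)), em = list(c(330, 45, 1)), qy = 0.18),
    tramadol      = list(abs = list(c(272, 28, 0.10)), em = list(c(302, 35, 1)), qy = 0.30),
    oxycodone     = list(abs = list(c(284, 30, 0.35)), em = list(c(340, 45, 1)), qy = 0.24),
    buprenorphine = list(abs = list(c(287, 32, 1.3)), em = list(c(348, 44, 1)), qy = 0.26),
    dihydrocodeine = list(abs = list(c(280, 28, 0.12)), em = list(c(315, 38, 1)), qy = 0.27),
    # --- party drugs and other NPS ---------------------------------------
    cocaine       = list(abs = list(c(274, 26, 0.8)), em = list(c(312, 34, 1)), qy = 0.22),
    ketamine      = list(abs = list(c(269, 28, 0.6)), em = list(c(298, 32, 1)), qy = 0.12),
    # second seized ketamine lot: same parent fluorophore plus an impurity band
    ketamine_b    = list(abs = list(c(269, 28, 0.6), c(330, 40, 0.15)),
                         em = list(c(298, 32, 1), c(410, 60, 0.35)), qy = 0.12),
    mdma          = list(abs = list(c(286, 30, 0.9)), em = list(c(322, 40, 1)), qy = 0.20),
    mephedrone    = list(abs = list(c(263, 27, 1.0)), em = list(c(307, 36, 1)), qy = 0.19),
    `2cb`         = list(abs = list(c(297, 33, 1.2)), em = list(c(338, 46, 1)), qy = 0.21),
    # --- cutting agents and nondrug controls ------------------------------
    caffeine      = list(abs = list(c(265, 28, 1.1)), em = list(c(310, 36, 1)), qy = 0.09),
    paracetamol   = list(abs = list(c(285, 30, 0.09)), em = list(c(325, 40, 1)), qy = 0.13),
    ibuprofen     = list(abs = list(c(265, 10, 0.050), c(275, 10, 0.060), c(285, 10, 0.050)),
                         em = list(c(292, 22, 1)), qy = 0.11),
    white_paper   = list(abs = list(c(370, 60, 0.8)), em = list(c(440, 90, 1)), qy = 0.60),
    lactose       = list(abs = list(c(260, 40, 0.02)), em = list(c(340, 80, 1)), qy = 0.03),
    cellulose     = list(abs = list(c(270, 45, 0.02)), em = list(c(360, 85, 1)), qy = 0.03)
  )
}

# Deterministic filler compounds standing in for the unnamed remainder of the
# 86-class library: optics generated from the index by a fixed formula so the
# pool is reproducible without stored data.
filler_compound_params <- function(k) {
  abs_center <- 256 + ((k * 13) %% 140)
  em_center  <- min(620, abs_center + 40 + ((k * 29) %% 130))
  list(abs = list(c(abs_center, 28 + 4 * (k %% 5), 0.8 + 0.06 * (k %% 7))),
       em  = list(c(em_center, 42 + 5 * (k %% 6), 1)),
       qy  = 0.08 + 0.02 * (k %% 9))
}

pool_cache <- new.env(parent = emptyenv())

#' Packaged compound pool
#'
#' Returns the named list of `hsf_fluorophore` objects that the default
#' class registry draws from: named stand-ins for the benzodiazepines,
#' opioids, nitazenes, cutting agents and nondrug controls plus 24
#' deterministic filler compounds (`nps_01` ... `nps_24`).
#'
#' @return Named list of `hsf_fluorophore` objects.
#' @export
compound_pool <- function() {
  if (!is.null(pool_cache$pool)) return(pool_cache$pool)
  tab <- compound_table()
  for (k in 1:24)
    tab[[sprintf("nps_%02d", k)]] <- filler_compound_params(k)
  pool <- lapply(names(tab), function(nm) {
    p <- tab[[nm]]
    fluorophore_spec(nm, p$abs, p$em, p$qy)
  })
  names(pool) <- names(tab)
  pool_cache$pool <- pool
  pool
}

#' Build a sample from compound names and concentrations
#'
#' @param ... Named concentrations in mg/mL, e.g.
#'   `make_sample(diazepam = 1, caffeine = 0.25)`. No arguments gives blank
#'   solvent.
#' @param solvent_baseline,path_length Passed to [sample_spec()].
#' @return An `hsf_sample`.
#' @export
make_sample <- function(..., solvent_baseline = 0.9, path_length = 1) {
  conc <- c(...)
  pool <- compound_pool()
  if (length(conc)) {
    unknown <- setdiff(names(conc), names(pool))
    if (length(unknown))
      stop("unknown compound name(s): ", paste(unknown, collapse = ", "))
  }
  comps <- lapply(names(conc), function(nm) list(pool[[nm]], unname(conc[nm])))
  sample_spec(comps, solvent_baseline = solvent_baseline,
              path_length = path_length)
}
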