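# Physics-based scan simulator. One channel = reflected LED line (a
# "pseudoabsorption" measurement: attenuated by 10^(-k_r A(lambda_ex))) plus
# fluorescence emission subject to the primary inner-filter factor
# (1 - 10^(-A(lambda_ex))) and secondary re-absorption 10^(-k_s A(lambda)).

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed < 2^31 from a master seed and identifiers.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p, "|")))
      h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}

# Precompute everything about a sample that does not depend on the LED:
# absorbance on the emission axis, per-component emission profiles, and
# per-component absorption at each LED centre.
sample_optics <- function(sample, config) {
  axis <- config$emission_axis
  ncomp <- length(sample$components)
  A_axis <- total_absorbance(sample, axis)
  em_prof <- matrix(0, nrow = length(axis), ncol = max(1L, ncomp))
  eps_led <- matrix(0, nrow = 12L, ncol = max(1L, ncomp))
  conc <- numeric(max(1L, ncomp))
  qy <- numeric(max(1L, ncomp))
  for (i in seq_len(ncomp)) {
    fl <- sample$components[[i]][[1]]
    conc[i] <- sample$components[[i]][[2]]
    qy[i] <- fl$quantum_yield
    em_prof[, i] <- fl$emission_profile(axis)
    eps_led[, i] <- fl$absorption(config$led_wavelengths)
  }
  list(axis = axis, A_axis = A_axis, em_prof = em_prof, eps_led = eps_led,
       conc = conc, qy = qy, ncomp = ncomp)
}

# Noiseless expected signal rate (counts per unit exposure) for one LED.
channel_rate <- function(sample, led_index, config, optics = NULL) {
  if (is.null(optics)) optics <- sample_optics(sample, config)
  li <- led_index + 1L
  lam_ex <- config$led_wavelengths[li]
  axis <- optics$axis
  # absorbance at the excitation line
  A_ex <- if (optics$ncomp)
    sample$path_length * sum(optics$eps_led[li, ] * optics$conc) else 0
  # reflected excitation line, attenuated by double-pass pseudoabsorption
  refl <- config$led_power[li] * sample$solvent_baseline *
    gauss_peak(axis, lam_ex, config$led_bandwidth_fwhm) *
    10^(-config$reflectance_path_factor * A_ex)
  # fluorescence: absorbed fraction split by each component's share of
  # absorbance at the excitation wavelength, times quantum yield and profile,
  # re-absorbed on the way out (secondary inner filter)
  fluo <- 0
  if (optics$ncomp && A_ex > 0) {
    contrib <- optics$eps_led[li, ] * optics$conc
    w <- contrib / sum(contrib)
    mix <- drop(optics$em_prof %*% (w * optics$qy))
    fluo <- config$emission_gain * config$led_power[li] * (1 - 10^(-A_ex)) *
      mix * 10^(-config$secondary_filter_factor * optics$A_axis)
  }
  refl + fluo
}

#' Simulate one LED channel of the device
#'
#' Produces the emission spectrum recorded while a single LED is active:
#' the reflected excitation line (a Gaussian at the LED centre, attenuated
#' by the concentration-dependent pseudoabsorption term), the fluorescence
#' band (inner-filter limited), plus seeded detector noise, clipped at
#' detector saturation.
#'
#' @param sample An `hsf_sample`.
#' @param led_index LED index, 0--11.
#' @param config An `hsf_device`.
#' @param integration_time Exposure, arbitrary time units, > 0.
#' @param brightness LED duty cycle in \[0, 1\]; default from `config`.
#' @param seed Integer seed for the noise draw.
#' @return Object of class `hsf_spectrum` with fields `led_index`,
#'   `intensities` (length 1516), `integration_time`, `brightness`,
#'   `saturated_flag`.
#' @export
simulate_channel <- function(sample, led_index, config,
                             integration_time,
                             brightness = config$brightness,
                             seed = 1L) {
  stopifnot(inherits(sample, "hsf_sample"), inherits(config, "hsf_device"))
  if (!(led_index %in% 0:11)) stop("led_index must be an integer in 0..11")
  if (integration_time <= 0) stop("integration_time must be positive")
  if (brightness < 0 || brightness > 1) stop("brightness must lie in [0, 1]")

  signal <- integration_time * brightness *
    channel_rate(sample, led_index, config)
  noisy <- if (config$noise_floor > 0 || config$shot_noise_scale > 0) {
    sd <- sqrt(config$noise_floor^2 + config$shot_noise_scale * signal)
    with_seed(seed, signal + stats::rnorm(length(signal), 0, sd))
  } else signal
  clipped <- pmin(pmax(noisy, 0), config$saturation_level)

  structure(list(led_index = as.integer(led_index),
                 intensities = clipped,
                 integration_time = integration_time,
                 brightness = brightness,
                 saturated_flag = any(noisy >= config$saturation_level)),
            class = "hsf_spectrum")
}

#' Auto-integration: expose until the detector reaches 80% saturation
#'
#' Mimics the device's acquisition loop: starting from a fixed exposure,
#' the integration time is rescaled multiplicatively
#' (`t <- t * target * saturation / peak`), assuming signal linear in
#' exposure, until the brightest pixel sits at the target fraction of
#' saturation (default 0.8, tolerance 2%). If the target is unreachable at
#' `max_integration` the longest exposure is returned with
#' `target_unreached = TRUE`.
#'
#' @inheritParams simulate_channel
#' @return An `hsf_spectrum` with extra fields `iterations` and
#'   `target_unreached`.
#' @export
auto_integrate <- function(sample, led_index, config, seed = 1L,
                           brightness = config$brightness) {
  stopifnot(inherits(config, "hsf_device"))
  optics <- sample_optics(sample, config)
  target <- config$target_saturation_fraction * config$saturation_level
  t_cur <- config$start_integration
  spec <- NULL
  unreached <- FALSE
  for (it in seq_len(config$integration_iterations_cap)) {
    spec <- simulate_channel_fast(sample, led_index, config, t_cur,
                                  brightness, derive_seed(seed, "iter", it),
                                  optics)
    peak <- max(spec$intensities)
    if (peak <= 0) {             # all-dark: nothing to expose for
      t_cur <- config$max_integration
      spec <- simulate_channel_fast(sample, led_index, config, t_cur,
                                    brightness, derive_seed(seed, "dark"),
                                    optics)
      unreached <- max(spec$intensities) < 0.98 * target
      it <- it + 1L
      break
    }
    if (abs(peak - target) <= 0.02 * config$saturation_level) break
    t_new <- t_cur * target / peak
    t_new <- min(t_new, config$max_integration)
    if (t_new == t_cur) {        # pinned at max exposure, still short
      unreached <- peak < 0.98 * target
      break
    }
    t_cur <- t_new
  }
  if (max(spec$intensities) < 0.98 * target &&
      spec$integration_time >= config$max_integration)
    unreached <- TRUE
  spec$iterations <- it
  spec$target_unreached <- unreached
  spec
}

# internal variant reusing precomputed optics
simulate_channel_fast <- function(sample, led_index, config, integration_time,
                                  brightness, seed, optics) {
  signal <- integration_time * brightness *
    channel_rate(sample, led_index, config, optics)
  noisy <- if (config$noise_floor > 0 || config$shot_noise_scale > 0) {
    sd <- sqrt(config$noise_floor^2 + config$shot_noise_scale * signal)
    with_seed(seed, signal + stats::rnorm(length(signal), 0, sd))
  } else signal
  clipped <- pmin(pmax(noisy, 0), config$saturation_level)
  structure(list(led_index = as.integer(led_index), intensities = clipped,
                 integration_time = integration_time, brightness = brightness,
                 saturated_flag = any(noisy >= config$saturation_level)),
            class = "hsf_spectrum")
}

#' Acquire a full raw scan (12 LED channels, 18,192 rows)
#'
#' Runs the auto-integration loop for each of the 12 LEDs in order and
#' assembles the device's raw data dialect: one block of 1516 rows per LED,
#' five fields per row (`led_index`, `emission_nm`, `intensity`,
#' `integration_time`, `brightness`).
#'
#' @param sample An `hsf_sample`.
#' @param config An `hsf_device`.
#' @param seed Integer master seed; the per-channel noise seeds are derived
#'   from it, so the same seed gives a bit-identical scan.
#' @param sample_id Optional identifier stored in the scan metadata.
#' @return Object of class `hsf_scan`: a data.frame of 18,192 rows x 5
#'   columns with attributes `seed` and `sample_id`.
#' @export
#' @examples
#' cfg <- device_config()
#' sc <- acquire_scan(make_sample(diazepam = 0.5), cfg, seed = 1)
#' nrow(sc)  # 18192
acquire_scan <- function(sample, config, seed = 1L, sample_id = NA_character_) {
  stopifnot(inherits(sample, "hsf_sample"), inherits(config, "hsf_device"))
  blocks <- lapply(0:11, function(li) {
    sp <- auto_integrate(sample, li, config,
                         seed = derive_seed(seed, "led", li))
    data.frame(led_index = sp$led_index,
               emission_nm = config$emission_axis,
               intensity = sp$intensities,
               integration_time = sp$integration_time,
               brightness = sp$brightness)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("hsf_scan", "data.frame")
  out
}

#' Write / read a raw scan as delimited text
#'
#' UTF-8 comma-separated text with a header line and exactly the five scan
#' columns; values are written with six significant digits, so a round trip
#' is lossless to that precision. Reading is header-driven: column order in
#' the file does not matter.
#'
#' @param scan An `hsf_scan`.
#' @param path File path.
#' @return `read_scan` returns an `hsf_scan`.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "hsf_scan"))
  df <- as.data.frame(scan)
  for (cl in c("emission_nm", "intensity", "integration_time", "brightness"))
    df[[cl]] <- signif(df[[cl]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("led_index", "emission_nm", "intensity", "integration_time",
            "brightness")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("scan file missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  validate_scan(df)
  class(df) <- c("hsf_scan", "data.frame")
  df
}

# Structural checks shared by readers and the preprocessing front door.
validate_scan <- function(scan) {
  if (nrow(scan) %% 12L != 0L)
    stop("malformed scan: row count ", nrow(scan), " is not 12 blocks")
  leds <- unique(scan$led_index)
  missing_leds <- setdiff(0:11, leds)
  if (length(missing_leds))
    stop("malformed scan: missing led_index ",
         paste(missing_leds, collapse = ", "))
  for (li in 0:11) {
    blk <- scan[scan$led_index == li, ]
    if (length(unique(blk$integration_time)) != 1L ||
        length(unique(blk$brightness)) != 1L)
      stop("malformed scan: block for led_index ", li,
           " is not constant in integration_time/brightness")
  }
  invisible(TRUE)
}
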