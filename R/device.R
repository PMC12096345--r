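#' Device configuration for the simulated HSF scanner
#'
#' Describes the optical and detector geometry of the portable scanner that
#' the simulator emulates: a ring of 12 UV LEDs (255--400 nm) exciting the
#' sample and a compact spectrometer recording emission on a fixed grid of
#' 1516 wavelengths spanning 185--655 nm, so that one full scan is
#' 12 x 1516 = 18,192 rows.
#'
#' @param led_wavelengths Numeric vector of exactly 12 LED centre
#'   wavelengths in nm, strictly increasing, all within \[255, 400\].
#'   Default: 12 evenly spaced values over that range.
#' @param led_bandwidth_fwhm Full width at half maximum of each LED line,
#'   nm. Default 12.
#' @param led_power Relative optical power per LED; length 1 or 12.
#'   Default 1.
#' @param emission_range Two-element numeric, nm span of the detector.
#'   Default c(185, 655).
#' @param emission_points Number of detector pixels. Default 1516 (forced
#'   by the 18,192-row scan format: 18192 / 12 LEDs).
#' @param saturation_level Detector counts at clipping. Default 65535
#'   (16-bit).
#' @param target_saturation_fraction Auto-integration target as a fraction
#'   of saturation, in (0, 1). Default 0.8.
#' @param reflectance_path_factor Effective Beer-Lambert exponent k_r
#'   applied to the reflected LED line (light traverses the well twice).
#'   Default 2.
#' @param secondary_filter_factor Effective exponent k_s for re-absorption
#'   of emitted light (secondary inner-filter effect). Default 0.5.
#' @param emission_gain Collection-efficiency factor applied to the
#'   fluorescence term relative to the reflected excitation line. The
#'   device geometry is arranged for approximate parity between the
#'   reflected-LED and emission signal sizes; with unit-area emission
#'   profiles (~0.02 nm^-1 at peak) and benzodiazepine-scale quantum
#'   yields, a gain of 50 puts typical samples in that regime. Default 50.
#' @param noise_floor Read-noise standard deviation, counts. Default 8.
#' @param shot_noise_scale Variance contributed per count of signal
#'   (Gaussian approximation to shot noise). Default 0.5.
#' @param start_integration Initial exposure used by the auto-integration
#'   loop, arbitrary time units. Default 1.
#' @param max_integration Longest allowed exposure. Default 1e8 (the LED
#'   power scale is ~1 count per time unit, so heavily absorbing samples
#'   need long exposures; dark channels still cap out and are flagged).
#' @param integration_iterations_cap Maximum auto-integration iterations.
#'   Default 8.
#' @param brightness LED duty cycle (PWM) in \[0, 1\] used for every
#'   channel. Default 1.
#'
#' @return An object of class `hsf_device`.
#' @export
#' @examples
#' cfg <- device_config()
#' length(cfg$emission_axis)  # 1516
device_config <- function(led_wavelengths = seq(255, 400, length.out = 12),
                          led_bandwidth_fwhm = 12,
                          led_power = 1,
                          emission_range = c(185, 655),
                          emission_points = 1516L,
                          saturation_level = 65535,
                          target_saturation_fraction = 0.8,
                          reflectance_path_factor = 2,
                          secondary_filter_factor = 0.5,
                          emission_gain = 50,
                          noise_floor = 8,
                          shot_noise_scale = 0.5,
                          start_integration = 1,
                          max_integration = 1e8,
                          integration_iterations_cap = 8L,
                          brightness = 1) {
  led_wavelengths <- as.numeric(led_wavelengths)
  if (length(led_wavelengths) != 12L)
    stop("exactly 12 LED wavelengths are required, got ",
         length(led_wavelengths))
  if (any(diff(led_wavelengths) <= 0))
    stop("LED wavelengths must be strictly increasing")
  if (any(led_wavelengths < 255 | led_wavelengths > 400))
    stop("LED wavelengths must lie within [255, 400] nm")
  if (!(target_saturation_fraction > 0 && target_saturation_fraction < 1))
    stop("target_saturation_fraction must lie in (0, 1)")
  if (emission_points < 2L) stop("emission_points must be >= 2")
  if (length(led_power) == 1L) led_power <- rep(led_power, 12L)
  if (length(led_power) != 12L)
    stop("led_power must have length 1 or 12")
  if (brightness < 0 || brightness > 1)
    stop("brightness must lie in [0, 1]")

  structure(list(
    led_wavelengths = led_wavelengths,
    led_bandwidth_fwhm = led_bandwidth_fwhm,
    led_power = led_power,
    emission_axis = seq(emission_range[1], emission_range[2],
                        length.out = emission_points),
    saturation_level = saturation_level,
    target_saturation_fraction = target_saturation_fraction,
    reflectance_path_factor = reflectance_path_factor,
    secondary_filter_factor = secondary_filter_factor,
    emission_gain = emission_gain,
    noise_floor = noise_floor,
    shot_noise_scale = shot_noise_scale,
    start_integration = start_integration,
    max_integration = max_integration,
    integration_iterations_cap = as.integer(integration_iterations_cap),
    brightness = brightness
  ), class = "hsf_device")
}

#' @export
print.hsf_device <- function(x, ...) {
  cat("<hsf_device> 12 LEDs", sprintf("%.0f-%.0f nm,", min(x$led_wavelengths),
      max(x$led_wavelengths)),
      length(x$emission_axis), "emission pixels",
      sprintf("%.0f-%.0f nm,", x$emission_axis[1],
              x$emission_axis[length(x$emission_axis)]),
      "saturation", x$saturation_level, "counts\n")
  invisible(x)
}

#' Write / read a device configuration as JSON
#'
#' The registry file is a plain-text JSON document so that a device
#' definition can be versioned alongside the scans it produced.
#'
#' @param config An `hsf_device`.
#' @param path File path.
#' @return `read_device_config` returns an `hsf_device`.
#' @export
write_device_config <- function(config, path) {
  stopifnot(inherits(config, "hsf_device"))
  out <- unclass(config)
  out$emission_range <- range(out$emission_axis)
  out$emission_points <- length(out$emission_axis)
  out$emission_axis <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_device_config
#' @export
read_device_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(device_config, raw)
}
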